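#' Augment a cohort with derived analysis columns
#'
#' Adds to the subject table the binary aspirin exposure derived from the
#' drug-event history, the dominant carrier indicator for one SNP, the
#' four-level joint exposure-by-genotype classification and its three
#' indicator columns (`exp_only`, `carrier_only`, `both`) against the
#' (unexposed, wild-type) reference.  Subjects with a missing genotype
#' call are excluded from that SNP's analysis table and counted.
#'
#' @param x a [cohort].
#' @param snp_id SNP to code (or `NULL` for exposure-only analyses).
#' @param drug_code,window_days passed to [derive_exposure()].
#' @param coding genotype coding, `"dominant"` (default) or `"codominant"`.
#' @return data frame of subjects with derived columns; the number of
#'   subjects dropped for missing genotype is in `attr(, "n_missing_genotype")`.
#' @export
augment_cohort <- function(x, snp_id = NULL, drug_code = "ASA",
                           window_days = 7, coding = "dominant") {
  d <- x$subjects
  expo <- derive_exposure(x, drug_code = drug_code, window_days = window_days)
  d$exposed <- expo$exposed[match(d$subject_id, expo$subject_id)]
  n_missing <- 0L
  if (!is.null(snp_id)) {
    cat_row <- x$snp_catalog[x$snp_catalog$snp_id == snp_id, ]
    if (!nrow(cat_row)) stop("unknown SNP: ", snp_id)
    d$carrier <- code_dominant(d[[snp_id]], cat_row$ref, cat_row$alt,
                               model = coding)
    miss <- is.na(d$carrier)
    n_missing <- sum(miss)
    d <- d[!miss, , drop = FALSE]
    jr <- joint_recode(d$exposed, as.integer(d$carrier > 0))
    d$joint <- jr
    d$exp_only <- as.integer(jr == "exp_only")
    d$carrier_only <- as.integer(jr == "carrier_only")
    d$both <- as.integer(jr == "both")
  }
  attr(d, "n_missing_genotype") <- n_missing
  d
}

#' Build a design matrix for the matched conditional likelihood
#'
#' Applies the complete-case rule on the model variables, drops matched
#' strata left without a case or without any control, expands factors to
#' indicator columns and removes columns that are constant within every
#' stratum (such terms are absorbed by the matching and carry no
#' information in the conditional likelihood).
#'
#' @param data subject-level data frame (typically from [augment_cohort()]).
#' @param formula right-hand-side formula of model terms.
#' @param outcome,stratum column names of the case indicator and the
#'   matched-stratum identifier.
#' @return an object of class `matched_design`: `X` (numeric matrix), `y`,
#'   `stratum` (factor), `assign`/`term_labels` (column-to-term map), and
#'   bookkeeping counts (`n_dropped_incomplete`, `n_strata_dropped`,
#'   `dropped_terms`).
#' @export
matched_design <- function(data, formula, outcome = "is_case",
                           stratum = "stratum_id") {
  vars <- all.vars(formula)
  miss <- setdiff(c(vars, outcome, stratum), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]

  # keep only informative strata: exactly one case plus >= 1 control
  keep <- unlist(lapply(split(seq_len(nrow(d)), d[[stratum]]), function(idx) {
    if (sum(d[[outcome]][idx]) == 1L && length(idx) >= 2L) idx else integer(0)
  }), use.names = FALSE)
  n_strata_dropped <- length(unique(d[[stratum]])) -
    length(unique(d[[stratum]][keep]))
  d <- d[sort(keep), , drop = FALSE]
  if (!nrow(d)) stop("no informative stratum left after complete-case filtering")

  for (v in vars) if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  mm <- stats::model.matrix(formula, d)
  asn <- attr(mm, "assign")
  labels <- attr(stats::terms(formula), "term.labels")
  X <- mm[, asn != 0L, drop = FALSE]
  asn <- asn[asn != 0L]

  str <- factor(d[[stratum]])
  dropped <- character(0)
  if (ncol(X)) {
    grp_mean <- rowsum(X, str) / as.vector(table(str))
    dev <- abs(X - grp_mean[as.integer(str), , drop = FALSE])
    const <- apply(dev, 2L, max) < 1e-12
    if (any(const)) {
      dropped <- unique(labels[asn[const]])
      message("dropping stratum-constant term(s): ", paste(dropped, collapse = ", "))
      X <- X[, !const, drop = FALSE]
      asn <- asn[!const]
    }
  }
  structure(list(
    X = X, y = as.integer(d[[outcome]]), stratum = str,
    assign = asn, term_labels = labels,
    n_obs = nrow(X), n_strata = nlevels(str),
    n_dropped_incomplete = sum(!cc), n_strata_dropped = n_strata_dropped,
    dropped_terms = dropped), class = "matched_design")
}

#' @export
print.matched_design <- function(x, ...) {
  cat(sprintf("Matched design: %d subjects in %d strata, %d column(s): %s\n",
              x$n_obs, x$n_strata, ncol(x$X),
              paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

term_columns <- function(design, label) {
  which(design$assign %in% which(design$term_labels == label))
}

drop_design_terms <- function(design, labels) {
  cols <- unlist(lapply(labels, term_columns, design = design))
  if (!length(cols)) return(design)
  design$X <- design$X[, -cols, drop = FALSE]
  design$assign <- design$assign[-cols]
  design
}

#' Matched-set conditional log-likelihood, gradient and Hessian
#'
#' For 1:m matched strata with exactly one case each, the conditional
#' probability that the observed case is the case among its matched set is
#' `exp(x_case' beta) / sum_j exp(x_j' beta)`.  The log-likelihood is the
#' sum of these log-probabilities over strata; stratum-constant covariates
#' cancel, which is what absorbs the matching variables.  Gradient and
#' Hessian are the exact analytic derivatives (the Hessian is the negative
#' sum of within-stratum covariance matrices of the rows, so the
#' likelihood is concave).
#'
#' @param beta coefficient vector (log-odds scale), one per design column.
#' @param design a [matched_design()].
#' @return list with `value`, `gradient`, `hessian`.
#' @export
conditional_loglik <- function(beta, design) {
  X <- design$X; y <- design$y; g <- design$stratum
  stopifnot(length(beta) == ncol(X))
  per_str <- rowsum(y, g)
  if (any(per_str != 1L)) {
    stop("every stratum must contain exactly one case (found counts ",
         paste(unique(per_str), collapse = ","), ")")
  }
  eta <- as.vector(X %*% beta)
  gi <- as.integer(g)
  mx <- as.vector(tapply(eta, g, max))
  lse <- mx + log(as.vector(rowsum(exp(eta - mx[gi]), g)))
  value <- sum(eta[y == 1L]) - sum(lse)
  p <- exp(eta - lse[gi])
  grad <- colSums(X[y == 1L, , drop = FALSE]) - as.vector(crossprod(X, p))
  M <- rowsum(X * p, g)                       # per-stratum E[x]
  H <- -(crossprod(X, X * p) - crossprod(M))
  list(value = value, gradient = grad, hessian = H)
}

#' Fit the matched conditional logistic model
#'
#' Newton-Raphson maximization of [conditional_loglik()] with
#' step-halving.  The variance-covariance matrix is the inverse of the
#' negative Hessian at the optimum.  Coefficients drifting beyond
#' `separation_bound` on the log-odds scale are reported as (quasi-)
#' complete separation via a warning, never silently returned.
#'
#' @param design a [matched_design()].
#' @param init starting values (default 0).
#' @param tol convergence tolerance on the score (`max |gradient| < tol`).
#' @param rel_tol alternative convergence rule on the relative
#'   log-likelihood change.
#' @param max_iter maximum Newton iterations; exceeding it raises a fit
#'   error carrying the iteration trace.
#' @param separation_bound |coefficient| threshold for the separation
#'   diagnostic (log-odds scale).
#' @return an object of class `cond_fit`: `coefficients`, `vcov`,
#'   `loglik`, `n_strata_used`, `n_obs`, `converged`, `iterations`,
#'   `separation` (offending term names, if any) and the `design` used.
#' @export
fit_conditional_logistic <- function(design, init = NULL, tol = 1e-8,
                                     rel_tol = 1e-10, max_iter = 100,
                                     separation_bound = 15) {
  p <- ncol(design$X)
  if (!p) stop("design has no estimable column")
  beta <- if (is.null(init)) numeric(p) else init
  stopifnot(length(beta) == p)
  ll <- conditional_loglik(beta, design)
  trace <- data.frame(iter = 0L, loglik = ll$value, max_score = max(abs(ll$gradient)))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(-ll$hessian, ll$gradient), error = function(e) {
      stop("singular Hessian at iteration ", iter,
           "; collinear terms or separated data", call. = FALSE)
    })
    new_beta <- beta + step
    new_ll <- conditional_loglik(new_beta, design)
    halvings <- 0L
    while ((!is.finite(new_ll$value) || new_ll$value < ll$value) && halvings < 25L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- conditional_loglik(new_beta, design)
      halvings <- halvings + 1L
    }
    rel_change <- abs(new_ll$value - ll$value) / (abs(ll$value) + 1e-12)
    beta <- new_beta; ll <- new_ll
    trace <- rbind(trace, data.frame(iter = iter, loglik = ll$value,
                                     max_score = max(abs(ll$gradient))))
    if (max(abs(ll$gradient)) < tol || rel_change < rel_tol) {
      converged <- TRUE
      break
    }
    if (any(abs(beta) > separation_bound)) break
  }
  sep <- colnames(design$X)[abs(beta) > separation_bound]
  if (length(sep)) {
    warning("possible complete separation: |coefficient| > ", separation_bound,
            " for ", paste(sep, collapse = ", "))
  }
  if (!converged && !length(sep)) {
    cond <- structure(class = c("reriscan_fit_error", "error", "condition"),
                      list(message = paste0("no convergence after ", max_iter,
                                            " Newton iterations"),
                           call = sys.call(-1), trace = trace))
    stop(cond)
  }
  vc <- solve(-ll$hessian)
  dimnames(vc) <- list(colnames(design$X), colnames(design$X))
  structure(list(
    coefficients = stats::setNames(beta, colnames(design$X)), vcov = vc,
    loglik = ll$value, score = ll$gradient,
    n_strata_used = design$n_strata, n_obs = design$n_obs,
    converged = converged, iterations = iter, separation = sep,
    trace = trace, design = design), class = "cond_fit")
}

#' @export
coef.cond_fit <- function(object, ...) object$coefficients

#' @export
vcov.cond_fit <- function(object, ...) object$vcov

#' @export
logLik.cond_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_strata_used, class = "logLik")
}

#' @export
print.cond_fit <- function(x, ...) {
  cat(sprintf("Conditional logistic fit: %d strata (%d subjects), loglik %.4f, %s in %d iteration(s)\n",
              x$n_strata_used, x$n_obs, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(summary(x)$table, digits = 4)
  invisible(x)
}

#' @export
summary.cond_fit <- function(object, conf_level = 0.95, ...) {
  b <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- b / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(coef = b, se = se, or = exp(b),
                    or_lo = exp(b - q * se), or_hi = exp(b + q * se),
                    z = z, p_value = 2 * stats::pnorm(-abs(z)))
  structure(list(table = tab, loglik = object$loglik,
                 n_strata_used = object$n_strata_used,
                 converged = object$converged), class = "summary.cond_fit")
}

#' @export
print.summary.cond_fit <- function(x, ...) {
  print(x$table, digits = 4)
  invisible(x)
}

#' Wald test of a block of model terms
#'
#' Chi-square Wald test `b' V^{-1} b` for all coefficients belonging to
#' one or more model terms (a multi-level factor contributes all of its
#' indicator columns).
#'
#' @param fit a [fit_conditional_logistic()] result.
#' @param terms character vector of term labels.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
wald_test <- function(fit, terms) {
  cols <- unlist(lapply(terms, term_columns, design = fit$design))
  if (!length(cols)) stop("term(s) not in fitted design: ",
                          paste(terms, collapse = ", "))
  b <- fit$coefficients[cols]
  V <- fit$vcov[cols, cols, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  df <- length(b)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# resample strata with replacement; duplicated strata get fresh ids so the
# conditional likelihood treats each draw as its own matched set
resample_design <- function(design, idx) {
  lev <- levels(design$stratum)[idx]
  rows <- split(seq_along(design$y), design$stratum)
  take <- rows[lev]
  n_per <- lengths(take)
  rix <- unlist(take, use.names = FALSE)
  new_stratum <- factor(rep(seq_along(take), n_per))
  out <- design
  out$X <- design$X[rix, , drop = FALSE]
  out$y <- design$y[rix]
  out$stratum <- new_stratum
  out$n_obs <- length(rix)
  out$n_strata <- length(take)
  out
}
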