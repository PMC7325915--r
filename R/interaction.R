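#' Joint exposure-by-genotype classification
#'
#' Maps binary exposure and carrier status to the four-level joint
#' classification used for additive-interaction analysis, with the
#' (unexposed, wild-type) cell as reference.  Missing input yields `NA`
#' (such subjects are excluded from that SNP's analysis by the design
#' builder and counted).
#'
#' @param exposed,carrier binary vectors (0/1).
#' @return factor with levels `ref`, `exp_only`, `carrier_only`, `both`.
#' @export
joint_recode <- function(exposed, carrier) {
  stopifnot(length(exposed) == length(carrier))
  ok <- !is.na(exposed) & !is.na(carrier)
  if (any(!exposed[ok] %in% 0:1) || any(!carrier[ok] %in% 0:1)) {
    stop("exposed and carrier must be binary 0/1")
  }
  lev <- c("ref", "exp_only", "carrier_only", "both")
  out <- rep(NA_integer_, length(exposed))
  out[ok] <- 1L + exposed[ok] + 2L * carrier[ok]
  factor(lev[out], levels = lev)
}

check_ors <- function(...) {
  v <- c(...)
  if (any(is.na(v)) || any(v <= 0)) stop("odds ratios must be positive")
  v
}

#' Relative excess risk due to interaction
#'
#' Departure from additivity of the joint odds ratios:
#' `RERI = OR11 - OR10 - OR01 + 1`, where `OR11` is the (exposed, carrier)
#' cell, `OR10` the (exposed, wild-type) cell and `OR01` the (unexposed,
#' carrier) cell, all against the (unexposed, wild-type) reference.
#' `RERI = 0` under exact additivity of odds-ratio excesses; positive
#' values indicate super-additive (synergistic) joint effects.
#'
#' @param or11,or10,or01 positive odds ratios (vectorized).
#' @return numeric RERI.
#' @export
reri <- function(or11, or10, or01) {
  check_ors(or11, or10, or01)
  or11 - or10 - or01 + 1
}

#' Synergism index
#'
#' Ratio of the joint excess odds to the sum of the single-factor excess
#' odds: `S = (OR11 - 1) / ((OR10 - 1) + (OR01 - 1))`.  `S > 1` indicates
#' positive additive interaction.  When the denominator is exactly zero S
#' is undefined and `NA` is returned; a negative denominator (one factor
#' protective) is allowed but flagged with a warning because S loses its
#' usual interpretation there.
#'
#' @inheritParams reri
#' @return numeric S (`NA` where undefined).
#' @export
synergy_index <- function(or11, or10, or01) {
  check_ors(or11, or10, or01)
  den <- (or10 - 1) + (or01 - 1)
  out <- ifelse(den == 0, NA_real_, (or11 - 1) / den)
  if (any(den < 0)) {
    warning("negative denominator: synergism index has no standard ",
            "interpretation when the single-factor excesses sum below zero")
  }
  out
}

#' Attributable proportion due to interaction
#'
#' `AP = RERI / OR11`: the share of the joint-cell odds ratio attributable
#' to interaction.
#'
#' @inheritParams reri
#' @export
attributable_proportion <- function(or11, or10, or01) {
  reri(or11, or10, or01) / or11
}

cell_terms <- c("exp_only", "carrier_only", "both")

check_joint_fit <- function(fit) {
  miss <- setdiff(cell_terms, names(fit$coefficients))
  if (length(miss)) {
    stop("fit lacks joint-classification term(s): ", paste(miss, collapse = ", "))
  }
}

contrast_or <- function(fit, w, conf_level) {
  # exp(w'beta) with delta (exact, log-linear) Wald interval
  est <- sum(w * fit$coefficients[names(w)])
  se <- sqrt(as.numeric(t(w) %*% fit$vcov[names(w), names(w)] %*% w))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(or = exp(est), lower = exp(est - q * se), upper = exp(est + q * se))
}

#' Four-cell and within-stratum odds ratios from a joint model
#'
#' Extracts the adjusted odds ratios of the joint
#' exposure-by-genotype classification (reference cell fixed at 1.00)
#' and the re-referenced within-stratum odds ratios: exposure within the
#' wild-type and within the carrier stratum, and carrier status within
#' the unexposed and within the exposed stratum.
#'
#' Two re-referencing modes are offered.  `"joint-model"` forms the
#' within-stratum ORs as coefficient contrasts of the joint model (e.g.
#' `OR(exposure | carrier) = OR11 / OR01` exactly), with the contrast's
#' delta-method CI.  `"stratified-refit"` refits the conditional model on
#' the subset of subjects defining each stratum, which lets the
#' adjustment covariates take stratum-specific coefficients.
#'
#' @param fit a converged [fit_conditional_logistic()] on the three
#'   joint-category indicators (plus covariates).
#' @param mode `"joint-model"` or `"stratified-refit"`.
#' @param data the augmented subject table (from [augment_cohort()]);
#'   required for `"stratified-refit"` and for the per-cell case/control
#'   counts.
#' @param formula model formula used for the refits (defaults to the
#'   joint indicators only if missing).
#' @param conf_level confidence level.
#' @return an object of class `stratum_ors`: `cells` data frame (cell,
#'   n_cases, n_controls, or, lower, upper) and `rereferenced` data frame,
#'   plus `mode`.
#' @export
stratum_ors <- function(fit, mode = c("joint-model", "stratified-refit"),
                        data = NULL, formula = NULL, conf_level = 0.95) {
  mode <- match.arg(mode)
  check_joint_fit(fit)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  cellrows <- lapply(cell_terms, function(tm) {
    w <- stats::setNames(1, tm)
    v <- contrast_or(fit, w, conf_level)
    data.frame(cell = tm, or = v[["or"]], lower = v[["lower"]],
               upper = v[["upper"]])
  })
  cells <- rbind(data.frame(cell = "ref", or = 1, lower = NA_real_,
                            upper = NA_real_),
                 do.call(rbind, cellrows))
  if (!is.null(data)) {
    tab <- table(data$joint, factor(data$is_case, levels = 0:1))
    cells$n_cases <- as.integer(tab[cells$cell, "1"])
    cells$n_controls <- as.integer(tab[cells$cell, "0"])
    cells <- cells[, c("cell", "n_cases", "n_controls", "or", "lower", "upper")]
  }

  rr_def <- list(
    exposure_in_wildtype = list(num = "exp_only", den = NULL,
                                subset = quote(carrier == 0), term = "exposed"),
    exposure_in_carrier = list(num = "both", den = "carrier_only",
                               subset = quote(carrier == 1), term = "exposed"),
    carrier_in_unexposed = list(num = "carrier_only", den = NULL,
                                subset = quote(exposed == 0), term = "carrier"),
    carrier_in_exposed = list(num = "both", den = "exp_only",
                              subset = quote(exposed == 1), term = "carrier"))
  rere <- lapply(names(rr_def), function(nm) {
    def <- rr_def[[nm]]
    if (mode == "joint-model") {
      w <- stats::setNames(1, def$num)
      if (!is.null(def$den)) w <- c(w, stats::setNames(-1, def$den))
      v <- contrast_or(fit, w, conf_level)
      data.frame(contrast = nm, or = v[["or"]], lower = v[["lower"]],
                 upper = v[["upper"]])
    } else {
      if (is.null(data)) stop("stratified-refit mode needs the augmented data")
      sub <- data[eval(def$subset, data), , drop = FALSE]
      covars <- if (is.null(formula)) character(0) else
        setdiff(all.vars(formula), c(cell_terms, "joint"))
      f <- stats::reformulate(c(def$term, covars))
      na_row <- data.frame(contrast = nm, or = NA_real_,
                           lower = NA_real_, upper = NA_real_)
      tryCatch({
        des <- suppressMessages(matched_design(sub, f))
        rfit <- suppressWarnings(fit_conditional_logistic(des))
        cols <- term_columns(rfit$design, def$term)
        # a separated refit has no usable within-stratum estimate
        if (any(colnames(rfit$design$X)[cols] %in% rfit$separation)) na_row
        else {
          b <- rfit$coefficients[cols[1]]
          se <- sqrt(rfit$vcov[cols[1], cols[1]])
          data.frame(contrast = nm, or = exp(b), lower = exp(b - q * se),
                     upper = exp(b + q * se))
        }
      }, error = function(e) na_row)
    }
  })
  structure(list(cells = cells, rereferenced = do.call(rbind, rere),
                 mode = mode, conf_level = conf_level),
            class = "stratum_ors")
}

#' @export
print.stratum_ors <- function(x, ...) {
  cat("Joint-classification odds ratios (reference = unexposed wild-type):\n")
  print(x$cells, digits = 4, row.names = FALSE)
  cat("Re-referenced within-stratum odds ratios (", x$mode, "):\n", sep = "")
  print(x$rereferenced, digits = 4, row.names = FALSE)
  invisible(x)
}

#' RERI and synergism index with confidence intervals
#'
#' Computes the additive-interaction measures from a fitted joint model.
#' With `method = "delta"` the RERI variance follows from the multivariate
#' delta method: writing `b10, b01, b11` for the three cell coefficients,
#' the gradient of RERI is `(-e^{b10}, -e^{b01}, e^{b11})` against the
#' 3x3 coefficient covariance, giving a symmetric Wald interval.  The S
#' interval is a delta interval on `ln S` (back-transformed), which
#' requires `OR11 > 1` and a positive excess-odds denominator; otherwise
#' the S interval is reported as undefined while the RERI interval
#' stands.  With `method = "bootstrap"` matched strata are resampled with
#' replacement, the model refitted, and percentile intervals taken --
#' an assumption-light check of the delta intervals.
#'
#' @param fit a converged [fit_conditional_logistic()] containing the
#'   three joint-category terms.
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed seed for the bootstrap resampling.
#' @param conf_level confidence level.
#' @return an object of class `interaction_estimate`: `reri`, `reri_ci`,
#'   `s`, `s_ci`, `ap`, `method`, and bootstrap metadata when used.
#' @export
interaction_ci <- function(fit, method = c("delta", "bootstrap"),
                           n_boot = 2000, seed = NULL, conf_level = 0.95) {
  method <- match.arg(method)
  check_joint_fit(fit)
  b <- fit$coefficients[cell_terms]
  ors <- exp(b)
  or10 <- ors[["exp_only"]]; or01 <- ors[["carrier_only"]]; or11 <- ors[["both"]]
  est_reri <- reri(or11, or10, or01)
  est_s <- suppressWarnings(synergy_index(or11, or10, or01))
  est_ap <- est_reri / or11
  alpha <- 1 - conf_level

  if (method == "delta") {
    V <- fit$vcov[cell_terms, cell_terms]
    grad <- c(-or10, -or01, or11)
    se_reri <- sqrt(as.numeric(t(grad) %*% V %*% grad))
    q <- stats::qnorm(1 - alpha / 2)
    reri_ci <- c(est_reri - q * se_reri, est_reri + q * se_reri)
    s_ci <- c(NA_real_, NA_real_)
    if (!is.na(est_s) && est_s > 0 && or11 > 1 && (or10 - 1) + (or01 - 1) > 0) {
      den <- (or10 - 1) + (or01 - 1)
      gs <- c(-or10 / den, -or01 / den, or11 / (or11 - 1))
      se_ls <- sqrt(as.numeric(t(gs) %*% V %*% gs))
      s_ci <- exp(c(log(est_s) - q * se_ls, log(est_s) + q * se_ls))
    }
    out <- list(reri = est_reri, reri_ci = reri_ci, se_reri = se_reri,
                s = est_s, s_ci = s_ci, ap = est_ap, method = "delta",
                conf_level = conf_level)
  } else {
    if (!is.null(seed)) set.seed(seed)
    design <- fit$design
    K <- design$n_strata
    reps <- matrix(NA_real_, n_boot, 2L)
    for (i in seq_len(n_boot)) {
      bs <- resample_design(design, sample.int(K, K, replace = TRUE))
      bfit <- tryCatch(
        suppressWarnings(fit_conditional_logistic(bs, init = fit$coefficients)),
        error = function(e) NULL)
      if (is.null(bfit)) next
      bb <- exp(bfit$coefficients[cell_terms])
      reps[i, 1L] <- bb[["both"]] - bb[["exp_only"]] - bb[["carrier_only"]] + 1
      den <- (bb[["exp_only"]] - 1) + (bb[["carrier_only"]] - 1)
      reps[i, 2L] <- if (den == 0) NA else (bb[["both"]] - 1) / den
    }
    ok <- !is.na(reps[, 1L])
    reri_ci <- unname(stats::quantile(reps[ok, 1L], c(alpha / 2, 1 - alpha / 2)))
    s_ok <- !is.na(reps[, 2L]) & reps[, 2L] > 0
    s_ci <- if (sum(s_ok) >= n_boot / 2) {
      unname(stats::quantile(reps[s_ok, 2L], c(alpha / 2, 1 - alpha / 2)))
    } else c(NA_real_, NA_real_)
    out <- list(reri = est_reri, reri_ci = reri_ci, s = est_s, s_ci = s_ci,
                ap = est_ap, method = "bootstrap", n_boot = n_boot,
                n_boot_ok = sum(ok), seed = seed, conf_level = conf_level)
  }
  structure(out, class = "interaction_estimate")
}

#' @export
print.interaction_estimate <- function(x, ...) {
  cat(sprintf("RERI = %.2f (%.0f%% CI %.2f to %.2f) [%s]\n", x$reri,
              100 * x$conf_level, x$reri_ci[1], x$reri_ci[2], x$method))
  if (is.na(x$s)) {
    cat("S undefined (single-factor excess odds sum to zero)\n")
  } else {
    cat(sprintf("S    = %.2f (%.0f%% CI %.2f to %.2f)\n", x$s,
                100 * x$conf_level, x$s_ci[1], x$s_ci[2]))
  }
  cat(sprintf("AP   = %.2f\n", x$ap))
  invisible(x)
}

#' Assemble a presentation table of interaction results
#'
#' Lays out per-SNP results the way additive-interaction analyses are
#' conventionally reported: per-cell case/control counts and odds ratios
#' with the reference cell printed as 1.00, the within-stratum odds
#' ratios, and RERI and S with intervals.  SNPs with fewer than
#' `min_cell` cases or controls in any analysis cell are segregated as
#' inconclusive rather than interpreted.
#'
#' @param results named list (by SNP) of lists with elements `stratum_ors`
#'   (a [stratum_ors()] with counts) and `interaction` (an
#'   [interaction_ci()] estimate).
#' @param min_cell minimum per-cell case and control count (default 5).
#' @param digits display rounding (default 2); applied here only, inputs
#'   keep full precision.
#' @return list with `main` and `inconclusive` data frames (one row per
#'   SNP x cell) sharing the same columns.
#' @export
knol_table <- function(results, min_cell = 5, digits = 2) {
  fmt <- function(v) round(v, digits)
  build <- function(snp, res) {
    so <- res$stratum_ors; ie <- res$interaction
    cells <- so$cells
    data.frame(
      snp_id = snp, cell = cells$cell,
      n_cases = cells$n_cases, n_controls = cells$n_controls,
      or = fmt(cells$or), or_lower = fmt(cells$lower),
      or_upper = fmt(cells$upper),
      reri = fmt(ie$reri), reri_lower = fmt(ie$reri_ci[1]),
      reri_upper = fmt(ie$reri_ci[2]),
      s = fmt(ie$s), s_lower = fmt(ie$s_ci[1]), s_upper = fmt(ie$s_ci[2]))
  }
  empty <- data.frame(snp_id = character(), cell = character(),
                      n_cases = integer(), n_controls = integer(),
                      or = numeric(), or_lower = numeric(), or_upper = numeric(),
                      reri = numeric(), reri_lower = numeric(),
                      reri_upper = numeric(), s = numeric(),
                      s_lower = numeric(), s_upper = numeric())
  main <- list(); inc <- list()
  for (snp in names(results)) {
    res <- results[[snp]]
    if (is.null(res$stratum_ors)) next
    if (is.null(res$stratum_ors$cells$n_cases)) {
      stop("knol_table needs per-cell counts; build stratum_ors with data")
    }
    blk <- build(snp, res)
    small <- min(c(blk$n_cases, blk$n_controls)) < min_cell
    if (small) inc[[snp]] <- blk else main[[snp]] <- blk
  }
  list(main = if (length(main)) do.call(rbind, c(main, make.row.names = FALSE))
         else empty,
       inconclusive = if (length(inc))
         do.call(rbind, c(inc, make.row.names = FALSE)) else empty)
}
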