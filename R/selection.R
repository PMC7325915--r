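#' Crude odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with the Woolf (log-scale normal) confidence
#' interval.  Any single zero cell triggers the Haldane-Anscombe 0.5
#' continuity correction (applied to all four cells and flagged); two
#' zero cells in the same row or column leave the OR undefined.
#'
#' @param a,b,c,d cell counts: exposed cases, exposed controls, unexposed
#'   cases, unexposed controls.
#' @param conf_level confidence level (default 0.95).
#' @return list with `or`, `lower`, `upper`, `corrected`.
#' @export
crude_or <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers")
  }
  zero <- cells == 0
  if ((zero["a"] && zero["b"]) || (zero["c"] && zero["d"]) ||
      (zero["a"] && zero["c"]) || (zero["b"] && zero["d"])) {
    stop("odds ratio undefined: two zero cells share a margin")
  }
  corrected <- any(zero)
  if (corrected) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(or), lower = unname(exp(log(or) - q * se)),
       upper = unname(exp(log(or) + q * se)), corrected = corrected)
}

#' Bivariate screening of candidate covariates
#'
#' Fits one matched conditional model per candidate (outcome against that
#' candidate alone) and keeps the candidates whose Wald p-value falls
#' below `alpha` (0.2 by default, the conventional permissive screen
#' before multivariable modelling).  Candidates that cannot be estimated
#' -- constant within every stratum, or failing to fit -- are excluded
#' and recorded.
#'
#' @param x a [cohort] or an augmented subject data frame.
#' @param candidates character vector of covariate column names.
#' @param alpha retention threshold on the Wald p-value.
#' @param ... passed to [augment_cohort()] when `x` is a cohort.
#' @return character vector of retained candidates (input order
#'   preserved) with a `details` attribute: data frame of candidate,
#'   p-value, status.
#' @export
screen_covariates <- function(x, candidates, alpha = 0.2, ...) {
  data <- if (inherits(x, "cohort")) augment_cohort(x, snp_id = NULL, ...) else x
  rows <- lapply(candidates, function(cand) {
    res <- tryCatch({
      des <- suppressMessages(
        matched_design(data, stats::reformulate(cand)))
      fit <- fit_conditional_logistic(des)
      data.frame(candidate = cand, p_value = wald_test(fit, cand)$p_value,
                 status = "ok")
    }, error = function(e) {
      data.frame(candidate = cand, p_value = NA_real_,
                 status = paste0("unestimable: ", conditionMessage(e)))
    })
    res
  })
  details <- do.call(rbind, rows)
  retained <- details$candidate[!is.na(details$p_value) &
                                  details$p_value < alpha]
  structure(retained, details = details)
}

#' Backward elimination with change-in-estimate and BIC guards
#'
#' Starting from the full model (exposure terms plus all candidates),
#' repeatedly tries to drop the candidate with the largest Wald p-value.
#' A drop is accepted only if (i) no exposure-term coefficient changes by
#' more than `cie` (relative change, log-odds scale by default) and
#' (ii) the Schwarz Bayesian Information Criterion
#' `-2 loglik + k log(n_strata)` improves.  When the worst candidate
#' fails the guards the next-worst is tried; elimination stops when no
#' remaining candidate can be dropped.  Exposure terms are never
#' candidates for removal.
#'
#' @param design a [matched_design()] containing exposure and candidate
#'   terms.
#' @param exposure_terms term labels of the main exposure(s), always kept.
#' @param candidates term labels eligible for removal.
#' @param cie change-in-estimate threshold (default 0.10).
#' @param scale scale of the change-in-estimate comparison:
#'   `"coefficient"` (log-odds, default) or `"or"`.
#' @param ... passed to [fit_conditional_logistic()].
#' @return list with `fit` (final `cond_fit`), `retained`, `dropped`, and
#'   `log` (one row per attempted drop with the decision and both guards).
#' @export
backward_eliminate <- function(design, exposure_terms, candidates,
                               cie = 0.10, scale = c("coefficient", "or"),
                               ...) {
  scale <- match.arg(scale)
  stopifnot(all(exposure_terms %in% design$term_labels))
  candidates <- intersect(candidates, unique(design$term_labels[design$assign]))
  fit <- fit_conditional_logistic(design, ...)
  bic <- function(f) -2 * f$loglik + length(f$coefficients) * log(f$n_strata_used)
  expo_coef <- function(f) {
    cols <- unlist(lapply(exposure_terms, term_columns, design = f$design))
    f$coefficients[cols]
  }
  rel_change <- function(old, new) {
    if (scale == "or") { old <- exp(old); new <- exp(new) }
    ifelse(old == new, 0, abs(new - old) / abs(old))
  }
  log_rows <- list()
  dropped <- character(0)
  repeat {
    if (!length(candidates)) break
    pvals <- vapply(candidates, function(cand) wald_test(fit, cand)$p_value, 0)
    accepted <- FALSE
    for (cand in candidates[order(pvals, decreasing = TRUE)]) {
      red_design <- drop_design_terms(fit$design, cand)
      red_fit <- tryCatch(fit_conditional_logistic(red_design, ...),
                          error = function(e) NULL)
      if (is.null(red_fit)) next
      delta <- max(rel_change(expo_coef(fit), expo_coef(red_fit)))
      bic_ok <- bic(red_fit) < bic(fit)
      cie_ok <- delta <= cie
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        candidate = cand, p_value = pvals[[cand]],
        bic_before = bic(fit), bic_after = bic(red_fit),
        max_exposure_change = delta,
        action = if (bic_ok && cie_ok) "dropped" else "kept")
      if (bic_ok && cie_ok) {
        fit <- red_fit
        dropped <- c(dropped, cand)
        candidates <- setdiff(candidates, cand)
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  list(fit = fit, retained = candidates, dropped = dropped,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(candidate = character(), p_value = numeric(),
                    bic_before = numeric(), bic_after = numeric(),
                    max_exposure_change = numeric(), action = character()))
}
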