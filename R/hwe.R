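#' Genotype counts for one SNP
#'
#' Tabulates (homozygous reference, heterozygous, homozygous variant)
#' counts for a SNP, optionally restricted to controls or cases.  Missing
#' calls are excluded from the counts.
#'
#' @param x a [cohort].
#' @param snp_id SNP identifier present in the cohort's catalog.
#' @param subset `"controls"` (the usual HWE QC population), `"cases"`
#'   or `"all"`.
#' @return named integer vector `c(n_AA, n_Aa, n_aa)` where `a` is the
#'   variant allele; warns when every call is missing.
#' @export
genotype_counts <- function(x, snp_id, subset = c("controls", "cases", "all")) {
  subset <- match.arg(subset)
  cat_row <- x$snp_catalog[x$snp_catalog$snp_id == snp_id, ]
  if (!nrow(cat_row)) stop("unknown SNP: ", snp_id)
  s <- x$subjects
  s <- switch(subset, controls = s[s$is_case == 0, ], cases = s[s$is_case == 1, ],
              all = s)
  nvar <- code_dominant(s[[snp_id]], cat_row$ref, cat_row$alt, model = "codominant")
  counts <- c(n_AA = sum(nvar == 0L, na.rm = TRUE),
              n_Aa = sum(nvar == 1L, na.rm = TRUE),
              n_aa = sum(nvar == 2L, na.rm = TRUE))
  if (sum(counts) == 0L) warning("all genotype calls missing for ", snp_id)
  counts
}

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts with the HWE-expected counts at the
#' estimated allele frequency; 1 degree of freedom.  A monomorphic SNP
#' (allele frequency 0 or 1) returns `chi2 = 0`, `p = 1` with a
#' `monomorphic` flag instead of a division by zero.
#'
#' @param counts integer vector `(n_AA, n_Aa, n_aa)`.
#' @param snp_id optional label carried into the result.
#' @return an object of class `hwe_test`: counts, variant-allele frequency
#'   estimate, `chi2`, `df = 1`, `p_value`, `method`, `monomorphic`.
#' @export
hwe_chisq <- function(counts, snp_id = NA_character_) {
  counts <- check_hwe_counts(counts)
  n <- sum(counts)
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  if (p <= 0 || p >= 1) {
    return(new_hwe_test(snp_id, counts, p, 0, 1, "chi-square", monomorphic = TRUE))
  }
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((counts - expd)^2 / expd)
  new_hwe_test(snp_id, counts, p, chi2,
               stats::pchisq(chi2, df = 1, lower.tail = FALSE), "chi-square")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Full enumeration of the conditional distribution of the heterozygote
#' count given the allele counts (Levene-Haldane distribution); the
#' p-value sums the probabilities of all genotype configurations no more
#' probable than the observed one.  Preferable to [hwe_chisq()] when
#' expected counts are small.
#'
#' @inheritParams hwe_chisq
#' @return an object of class `hwe_test` with `method = "exact"`
#'   (`chi2` is `NA`).
#' @export
hwe_exact <- function(counts, snp_id = NA_character_) {
  counts <- check_hwe_counts(counts)
  n <- sum(counts)
  n_a <- 2 * counts[3] + counts[2]   # variant allele count
  p <- n_a / (2 * n)
  if (p <= 0 || p >= 1) {
    return(new_hwe_test(snp_id, counts, p, NA_real_, 1, "exact", monomorphic = TRUE))
  }
  n_minor <- min(n_a, 2 * n - n_a)
  het <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(n_het | n, n_minor) up to a shared constant
  lp <- lgamma(n + 1) - lgamma((n_minor - het) / 2 + 1) - lgamma(het + 1) -
    lgamma(n - (n_minor + het) / 2 + 1) + het * log(2)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- match(counts[2], het)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  pval <- min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
  new_hwe_test(snp_id, counts, p, NA_real_, pval, "exact")
}

check_hwe_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be three nonnegative genotype counts (n_AA, n_Aa, n_aa)")
  }
  if (sum(counts) < 1) stop("no genotyped subjects")
  counts
}

new_hwe_test <- function(snp_id, counts, p, chi2, pval, method,
                         monomorphic = FALSE) {
  structure(list(snp_id = snp_id,
                 counts = stats::setNames(counts, c("n_AA", "n_Aa", "n_aa")),
                 allele_freq_hat = unname(p), maf = unname(min(p, 1 - p)),
                 chi2 = unname(chi2), df = 1L, p_value = unname(pval),
                 method = method, monomorphic = monomorphic),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("HWE %s test%s: counts (%d, %d, %d), variant freq %.4f, %sp = %.4g%s\n",
              x$method, if (is.na(x$snp_id)) "" else paste0(" [", x$snp_id, "]"),
              x$counts[1], x$counts[2], x$counts[3], x$allele_freq_hat,
              if (is.na(x$chi2)) "" else sprintf("chi2 = %.4g, ", x$chi2),
              x$p_value, if (x$monomorphic) " (monomorphic)" else ""))
  invisible(x)
}

#' Genotyping call rate for one SNP
#'
#' @param x a [cohort].
#' @param snp_id SNP identifier.
#' @param threshold minimum acceptable call rate (default 0.98).
#' @return list with `rate` (non-missing calls / subjects) and `flagged`.
#' @export
call_rate <- function(x, snp_id, threshold = 0.98) {
  if (!snp_id %in% x$snp_catalog$snp_id) stop("unknown SNP: ", snp_id)
  v <- x$subjects[[snp_id]]
  rate <- mean(!is.na(v) & nzchar(v))
  list(rate = rate, flagged = rate < threshold)
}

#' Per-SNP quality-control table
#'
#' Runs genotype counting (in controls by default, the standard choice for
#' detecting selection bias), call rate, minor-allele frequency and the
#' HWE test for every SNP in the catalog.  SNPs are flagged -- never
#' dropped automatically -- when the HWE p-value falls below `alpha` or
#' the call rate below `call_rate_threshold`.
#'
#' @param x a [cohort].
#' @param subset population used for the HWE test (default controls).
#' @param method `"chi-square"` or `"exact"`.
#' @param alpha HWE flag threshold (default 0.001).
#' @param call_rate_threshold minimum call rate (default 0.98).
#' @return data frame with one row per SNP: counts, `maf`, `call_rate`,
#'   `chi2`, `p_value`, `flags` (`;`-separated, empty when clean).
#' @export
hwe_qc <- function(x, subset = "controls", method = c("chi-square", "exact"),
                   alpha = 0.001, call_rate_threshold = 0.98) {
  method <- match.arg(method)
  rows <- lapply(snp_ids(x), function(s) {
    counts <- tryCatch(suppressWarnings(genotype_counts(x, s, subset = subset)),
                       error = function(e) NULL)
    if (is.null(counts)) {
      return(data.frame(snp_id = s, n_AA = NA_integer_, n_Aa = NA_integer_,
                        n_aa = NA_integer_, maf = NA_real_,
                        call_rate = NA_real_, chi2 = NA_real_,
                        p_value = NA_real_, flags = "genotype_error"))
    }
    cr <- call_rate(x, s, threshold = call_rate_threshold)
    if (sum(counts) == 0L) {
      return(data.frame(snp_id = s, n_AA = 0L, n_Aa = 0L, n_aa = 0L,
                        maf = NA_real_, call_rate = cr$rate, chi2 = NA_real_,
                        p_value = NA_real_, flags = "no_calls"))
    }
    ht <- if (method == "chi-square") hwe_chisq(counts, s) else hwe_exact(counts, s)
    flags <- c(if (cr$flagged) "low_call_rate",
               if (ht$monomorphic) "monomorphic",
               if (!is.na(ht$p_value) && ht$p_value < alpha) "hwe_deviation")
    data.frame(snp_id = s, n_AA = counts[1], n_Aa = counts[2], n_aa = counts[3],
               maf = ht$maf, call_rate = cr$rate,
               chi2 = if (is.na(ht$chi2)) NA_real_ else ht$chi2,
               p_value = ht$p_value,
               flags = paste(flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
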