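#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end analysis run.  `covariates = "auto"`
#' runs the bivariate screen ([screen_covariates()]) followed by backward
#' elimination with the change-in-estimate and BIC guards
#' ([backward_eliminate()]); a character vector fixes the adjustment set;
#' `NULL` fits the joint classification alone.
#'
#' @param input path to a cohort table, or a [cohort] object.
#' @param schema optional column mapping for [read_cohort_table()].
#' @param exclusion_rules rules for [apply_exclusions()]; `NULL` skips.
#' @param snps SNP ids to analyse (`NULL` = all in the catalog).
#' @param covariates `"auto"`, a character vector, or `NULL`.
#' @param candidate_covariates candidate pool for `"auto"` selection.
#' @param drug_code,window_days exposure definition.
#' @param rereference_mode within-stratum OR mode for [stratum_ors()].
#' @param ci_method `"delta"` or `"bootstrap"` for [interaction_ci()].
#' @param n_boot bootstrap replicates when `ci_method = "bootstrap"`.
#' @param alpha_screen,cie screening threshold and change-in-estimate
#'   threshold for the automatic covariate procedure.
#' @param min_cell inconclusive-SNP cell-count threshold.
#' @param hwe_alpha HWE flag threshold.
#' @param seed seed (required when bootstrapping).
#' @param digits display rounding used at render time only.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, schema = NULL,
                       exclusion_rules = c("reliability_zero", "non_white",
                                           "control_prior_ugih"),
                       snps = NULL, covariates = NULL,
                       candidate_covariates = c("age", "bmi_class", "sex",
                                                "arthrosis", "h_pylori",
                                                "gi_history", "info_source",
                                                "n_interviews", "reliability"),
                       drug_code = "ASA", window_days = 7,
                       rereference_mode = "stratified-refit",
                       ci_method = "delta", n_boot = 2000,
                       alpha_screen = 0.2, cie = 0.10,
                       min_cell = 5, hwe_alpha = 0.001,
                       seed = NULL, digits = 2) {
  if (identical(ci_method, "bootstrap") && is.null(seed)) {
    stop("a seed is required when bootstrap confidence intervals are requested")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full interaction-analysis pipeline
#'
#' Stages, in fixed order: read (if needed) and validate the cohort;
#' apply exclusion rules; per-SNP quality control (counts, call rate,
#' HWE in controls); then per SNP: derive exposure, code the carrier
#' status, build the joint-classification design, select covariates (if
#' requested), fit the matched conditional logistic model, extract the
#' four-cell and within-stratum odds ratios, and estimate RERI and S with
#' intervals.  A failure in one SNP is logged and does not abort the run.
#'
#' @param config a [run_config()] (or a [cohort], used with defaults).
#' @param ... used to override `run_config` fields when `config` is a
#'   cohort.
#' @return an object of class `reri_run`: per-SNP `results` (each with
#'   `fit_summary`, `stratum_ors`, `interaction`, `n_missing_genotype`,
#'   or an `error` message), `hwe`, `exclusion_log`, `knol` (main +
#'   inconclusive tables), `config` echo and package `version`.
#' @export
run_pipeline <- function(config, ...) {
  if (inherits(config, "cohort")) config <- run_config(config, ...)
  stopifnot(inherits(config, "run_config"))
  ch <- config$input
  if (!inherits(ch, "cohort")) {
    ch <- read_cohort_table(ch, schema = config$schema)
  }
  if (!is.null(config$exclusion_rules)) {
    ch <- apply_exclusions(ch, rules = config$exclusion_rules)
  }
  hwe_tab <- hwe_qc(ch, alpha = config$hwe_alpha)
  snps <- if (is.null(config$snps)) snp_ids(ch) else config$snps

  # covariate policy resolved once, on the cohort without genotype columns
  covars <- config$covariates
  screened <- NULL
  if (identical(covars, "auto")) {
    screened <- screen_covariates(ch, config$candidate_covariates,
                                  alpha = config$alpha_screen,
                                  drug_code = config$drug_code,
                                  window_days = config$window_days)
    covars <- as.character(screened)
  }

  results <- stats::setNames(vector("list", length(snps)), snps)
  for (snp in snps) {
    results[[snp]] <- tryCatch(
      analyse_snp(ch, snp, covars, config,
                  auto = identical(config$covariates, "auto")),
      error = function(e) list(error = conditionMessage(e)))
  }
  ok <- Filter(function(r) is.null(r$error), results)
  knol <- knol_table(ok, min_cell = config$min_cell, digits = config$digits)
  structure(list(results = results, hwe = hwe_tab,
                 exclusion_log = ch$exclusion_log, knol = knol,
                 screen = attr(screened, "details"),
                 config = config,
                 version = as.character(utils::packageVersion("reriscan"))),
            class = "reri_run")
}

analyse_snp <- function(ch, snp, covars, config, auto = FALSE) {
  data <- augment_cohort(ch, snp_id = snp, drug_code = config$drug_code,
                         window_days = config$window_days)
  f <- stats::reformulate(c(cell_terms, covars))
  design <- suppressMessages(matched_design(data, f))
  if (auto && length(covars)) {
    elim <- backward_eliminate(design, exposure_terms = cell_terms,
                               candidates = setdiff(covars,
                                                    design$dropped_terms),
                               cie = config$cie)
    fit <- elim$fit
    kept <- elim$retained
    elim_log <- elim$log
  } else {
    fit <- fit_conditional_logistic(design)
    kept <- covars
    elim_log <- NULL
  }
  # analysis data restricted to the rows actually modelled
  vars <- all.vars(f)
  data_cc <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
                  drop = FALSE]
  so <- stratum_ors(fit, mode = config$rereference_mode, data = data_cc,
                    formula = stats::reformulate(c(cell_terms, kept)))
  ie <- interaction_ci(fit, method = config$ci_method,
                       n_boot = config$n_boot, seed = config$seed)
  list(snp_id = snp, fit_summary = summary(fit)$table,
       loglik = fit$loglik, converged = fit$converged,
       n_strata_used = fit$n_strata_used,
       covariates_retained = kept, elimination_log = elim_log,
       n_missing_genotype = attr(data, "n_missing_genotype"),
       stratum_ors = so, interaction = ie)
}

#' @export
print.reri_run <- function(x, ...) {
  ok <- Filter(function(r) is.null(r$error), x$results)
  failed <- setdiff(names(x$results), names(ok))
  cat(sprintf("Interaction pipeline run: %d SNP(s) analysed, %d failed\n",
              length(ok), length(failed)))
  for (snp in names(ok)) {
    ie <- ok[[snp]]$interaction
    cat(sprintf("  %s: RERI = %.2f (%.2f to %.2f), S = %s\n", snp, ie$reri,
                ie$reri_ci[1], ie$reri_ci[2],
                if (is.na(ie$s)) "undefined" else sprintf("%.2f", ie$s)))
  }
  if (length(failed)) {
    cat("Failed:", paste(failed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Render pipeline results to files
#'
#' Writes a machine-readable JSON with full-precision values, TSV and
#' Markdown presentation tables (rounded at render time only), the HWE
#' QC table and a manifest of the produced files.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @param formats subset of `c("json", "tsv", "md")`.
#' @return invisibly, the manifest data frame (file, bytes).
#' @export
render_report <- function(result, dir, formats = c("json", "tsv", "md")) {
  stopifnot(inherits(result, "reri_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  strip <- function(r) {
    if (!is.null(r$error)) return(list(error = r$error))
    list(snp_id = r$snp_id, loglik = r$loglik, converged = r$converged,
         n_strata_used = r$n_strata_used,
         covariates_retained = r$covariates_retained,
         n_missing_genotype = r$n_missing_genotype,
         cells = r$stratum_ors$cells,
         rereferenced = r$stratum_ors$rereferenced,
         reri = r$interaction$reri, reri_ci = r$interaction$reri_ci,
         s = r$interaction$s, s_ci = r$interaction$s_ci,
         ap = r$interaction$ap, ci_method = r$interaction$method)
  }
  if ("json" %in% formats) {
    path <- file.path(dir, "results.json")
    jsonlite::write_json(
      list(version = result$version,
           results = lapply(result$results, strip),
           hwe = result$hwe),
      path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    files <- c(files, path)
  }
  if ("tsv" %in% formats) {
    for (nm in c("main", "inconclusive")) {
      path <- file.path(dir, paste0("knol_", nm, ".tsv"))
      utils::write.table(result$knol[[nm]], path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
      files <- c(files, path)
    }
    path <- file.path(dir, "hwe_qc.tsv")
    utils::write.table(result$hwe, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    files <- c(files, path)
  }
  if ("md" %in% formats) {
    path <- file.path(dir, "knol.md")
    writeLines(knol_markdown(result$knol), path)
    files <- c(files, path)
  }
  manifest <- data.frame(file = basename(files),
                         bytes = file.size(files))
  utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

knol_markdown <- function(knol) {
  fmt_tab <- function(tab, title) {
    if (!nrow(tab)) return(c(paste0("## ", title), "", "_no SNPs_", ""))
    hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    body <- apply(tab, 1L, function(r) {
      r[is.na(r)] <- ""
      paste0("| ", paste(trimws(r), collapse = " | "), " |")
    })
    c(paste0("## ", title), "", hdr, sep, body, "")
  }
  c("# Additive interaction results", "",
    fmt_tab(knol$main, "Main results"),
    fmt_tab(knol$inconclusive, "Inconclusive (sparse cells)"))
}
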