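#' @keywords internal
"_PACKAGE"

# Canonical subject-level columns understood by the package.  Genotype
# columns (one per SNP, named by rs identifier) come on top of these.
.core_cols <- c("subject_id", "stratum_id", "is_case", "index_date")
.known_covariates <- c(
  "center", "period", "age", "sex", "bmi_class", "reliability",
  "ancestry_flag", "info_source", "n_interviews", "arthrosis", "h_pylori",
  "gi_history", "nsaid_non_aspirin", "ppi", "antiaggregant", "anticoagulant"
)

#' Construct a matched case-control cohort object
#'
#' A `cohort` bundles the validated subject table, the parsed drug-event
#' history, the SNP catalog (reference and variant allele per SNP) and an
#' exclusion log.  Each matched stratum holds exactly one case and one to
#' three controls recruited from the same center.
#'
#' @param subjects data frame with one row per subject.  Must contain
#'   `subject_id`, `stratum_id`, `is_case` (0/1) and `index_date` (`Date`);
#'   genotype columns are `"A/G"`-style allele pairs (or `NA`).
#' @param snp_catalog data frame with columns `snp_id`, `ref`, `alt`.
#' @param drug_events data frame with columns `subject_id`, `drug_code`,
#'   `date` (`Date`); may be empty.
#' @param exclusion_log data frame with columns `subject_id`, `rule`.
#' @param validate if `TRUE`, enforce the stratum invariants (one case,
#'   1-3 controls, shared center, no duplicated subject id).
#' @return an object of class `cohort`.
#' @export
cohort <- function(subjects, snp_catalog = NULL, drug_events = NULL,
                   exclusion_log = NULL, validate = TRUE) {
  if (is.null(drug_events)) {
    drug_events <- data.frame(subject_id = character(), drug_code = character(),
                              date = as.Date(character()))
  }
  if (is.null(exclusion_log)) {
    exclusion_log <- data.frame(subject_id = character(), rule = character())
  }
  if (is.null(snp_catalog)) {
    snp_catalog <- infer_snp_catalog(subjects)
  }
  obj <- structure(
    list(subjects = subjects, snp_catalog = snp_catalog,
         drug_events = drug_events, exclusion_log = exclusion_log),
    class = "cohort")
  if (validate) validate_cohort(obj) else obj
}

#' @export
print.cohort <- function(x, ...) {
  ns <- nrow(x$subjects)
  cat(sprintf("Matched case-control cohort: %d subjects, %d strata (%d cases), %d SNPs\n",
              ns, length(unique(x$subjects$stratum_id)),
              sum(x$subjects$is_case == 1), nrow(x$snp_catalog)))
  if (nrow(x$exclusion_log)) {
    cat(sprintf("Exclusion log: %d entries (%s)\n", nrow(x$exclusion_log),
                paste(names(sort(table(x$exclusion_log$rule), decreasing = TRUE)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
nobs.cohort <- function(object, ...) nrow(object$subjects)

snp_ids <- function(x) x$snp_catalog$snp_id

infer_snp_catalog <- function(subjects) {
  cand <- grep("^rs[0-9]+$", names(subjects), value = TRUE)
  if (!length(cand)) {
    return(data.frame(snp_id = character(), ref = character(), alt = character()))
  }
  rows <- lapply(cand, function(s) {
    al <- unlist(strsplit(stats::na.omit(as.character(subjects[[s]])), "/", fixed = TRUE))
    al <- al[nzchar(al)]
    if (!length(al)) return(data.frame(snp_id = s, ref = NA_character_, alt = NA_character_))
    tab <- sort(table(al), decreasing = TRUE)
    data.frame(snp_id = s, ref = names(tab)[1],
               alt = if (length(tab) > 1) names(tab)[2] else NA_character_)
  })
  do.call(rbind, rows)
}

validate_cohort <- function(x) {
  s <- x$subjects
  if (anyDuplicated(s$subject_id)) {
    stop("duplicated subject_id: ",
         paste(unique(s$subject_id[duplicated(s$subject_id)]), collapse = ", "))
  }
  if (!all(s$is_case %in% c(0L, 1L))) stop("is_case must be 0 or 1")
  spl <- split(seq_len(nrow(s)), s$stratum_id)
  for (idx in spl) {
    cs <- sum(s$is_case[idx])
    if (cs != 1L) {
      stop("stratum ", s$stratum_id[idx[1]], " has ", cs, " cases (need exactly 1)")
    }
    nc <- length(idx) - 1L
    if (nc < 1L || nc > 3L) {
      stop("stratum ", s$stratum_id[idx[1]], " has ", nc, " controls (need 1-3)")
    }
    if ("center" %in% names(s) && length(unique(s$center[idx])) != 1L) {
      stop("stratum ", s$stratum_id[idx[1]], " spans multiple centers")
    }
  }
  x
}

#' Read a delimited cohort table
#'
#' Reads a tab- or comma-delimited subject table (header row required),
#' applies an optional column-name mapping, types the core fields and
#' collects rows that fail coercion into the exclusion log instead of
#' dropping them silently.  Genotype cells are `"A/G"`-style allele pairs;
#' an empty cell or `"NA"` is a missing call (never recoded as wild-type).
#' Drug events are parsed from a `drug_events` column of
#' `"CODE@YYYY-MM-DD"` entries separated by `";"`.
#'
#' @param file path to a TSV/CSV file, or a character vector of lines.
#' @param schema optional named character vector mapping canonical column
#'   names (names) to the file's column names (values).
#' @param snp_catalog optional catalog data frame (`snp_id`, `ref`, `alt`);
#'   inferred from the observed alleles (major allele = reference) if absent.
#' @param sep field separator; guessed from the header when `NULL`.
#' @return a validated [cohort] object; malformed rows and malformed strata
#'   are recorded in `$exclusion_log`.
#' @export
read_cohort_table <- function(file, schema = NULL, snp_catalog = NULL, sep = NULL) {
  lines_mode <- length(file) > 1L || grepl("\n", file[1], fixed = TRUE)
  con <- if (lines_mode) textConnection(paste(file, collapse = "\n")) else file
  if (is.null(sep)) {
    hdr <- if (lines_mode) file[1] else readLines(file, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(con, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      pos <- match(schema[[canon]], names(raw))
      if (is.na(pos)) stop("schema refers to missing column '", schema[[canon]], "'")
      names(raw)[pos] <- canon
    }
  }
  miss <- setdiff(.core_cols, names(raw))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(raw$subject_id)) {
    stop("duplicated subject_id: ",
         paste(unique(raw$subject_id[duplicated(raw$subject_id)]), collapse = ", "))
  }

  excl <- data.frame(subject_id = character(), rule = character())
  bad <- function(rows, rule) {
    if (any(rows)) excl <<- rbind(excl, data.frame(subject_id = raw$subject_id[rows],
                                                   rule = rule))
    rows
  }
  is_case <- suppressWarnings(as.integer(raw$is_case))
  drop <- bad(is.na(is_case) | !(is_case %in% c(0L, 1L)), "bad_case_code")
  index_date <- as.Date(raw$index_date, format = "%Y-%m-%d")
  drop <- drop | bad(is.na(index_date) & !drop, "bad_index_date")
  if ("reliability" %in% names(raw)) {
    rel <- suppressWarnings(as.numeric(raw$reliability))
    bad_rel <- !is.na(raw$reliability) & nzchar(raw$reliability) &
      (is.na(rel) | rel < 0 | rel > 10)
    drop <- drop | bad(bad_rel & !drop, "bad_reliability")
  }

  subj <- raw[!drop, , drop = FALSE]
  subj$is_case <- is_case[!drop]
  subj$index_date <- index_date[!drop]
  for (col in c("age", "reliability", "n_interviews")) {
    if (col %in% names(subj)) subj[[col]] <- suppressWarnings(as.numeric(subj[[col]]))
  }
  geno_cols <- grep("^rs[0-9]+$", names(subj), value = TRUE)
  for (col in c(geno_cols, setdiff(.known_covariates, c("age", "reliability", "n_interviews")))) {
    if (col %in% names(subj)) {
      v <- as.character(subj[[col]])
      v[!nzchar(v) | v == "NA"] <- NA_character_
      subj[[col]] <- v
    }
  }

  events <- parse_drug_events(subj)
  subj$drug_events <- NULL

  # strata that no longer hold exactly one case and 1-3 controls are dropped
  keep <- rep(TRUE, nrow(subj))
  for (idx in split(seq_len(nrow(subj)), subj$stratum_id)) {
    ncase <- sum(subj$is_case[idx]); nctl <- length(idx) - ncase
    if (ncase != 1L || nctl < 1L || nctl > 3L) {
      keep[idx] <- FALSE
      excl <- rbind(excl, data.frame(subject_id = subj$subject_id[idx],
                                     rule = "bad_stratum_structure"))
    }
  }
  subj <- subj[keep, , drop = FALSE]
  events <- events[events$subject_id %in% subj$subject_id, , drop = FALSE]
  rownames(subj) <- NULL
  cohort(subj, snp_catalog = snp_catalog, drug_events = events,
         exclusion_log = excl)
}

parse_drug_events <- function(subj) {
  out <- data.frame(subject_id = character(), drug_code = character(),
                    date = as.Date(character()))
  if (!"drug_events" %in% names(subj)) return(out)
  ev <- as.character(subj$drug_events)
  has <- !is.na(ev) & nzchar(ev) & ev != "NA"
  if (!any(has)) return(out)
  per <- strsplit(ev[has], ";", fixed = TRUE)
  n <- lengths(per)
  flat <- unlist(per)
  parts <- strsplit(flat, "@", fixed = TRUE)
  ok <- lengths(parts) == 2L
  if (!all(ok)) stop("malformed drug event entry: ", flat[!ok][1])
  code <- vapply(parts, `[`, "", 1L)
  date <- as.Date(vapply(parts, `[`, "", 2L), format = "%Y-%m-%d")
  if (anyNA(date)) stop("invalid drug event date: ", flat[is.na(date)][1])
  data.frame(subject_id = rep(subj$subject_id[has], n),
             drug_code = code, date = date)
}

#' Write a cohort back to a delimited table
#'
#' Inverse of [read_cohort_table()]: one row per subject, drug events
#' re-encoded as `"CODE@YYYY-MM-DD"` entries joined with `";"`, missing
#' values as empty cells.
#'
#' @param x a [cohort].
#' @param file output path, or `NULL` to return the lines invisibly.
#' @param sep field separator (default tab).
#' @export
write_cohort <- function(x, file = NULL, sep = "\t") {
  s <- x$subjects
  ev <- x$drug_events
  if (nrow(ev)) {
    ev <- ev[order(ev$subject_id, ev$date, ev$drug_code), ]
    enc <- vapply(split(paste0(ev$drug_code, "@", format(ev$date)), ev$subject_id),
                  paste, "", collapse = ";")
    s$drug_events <- unname(enc[match(s$subject_id, names(enc))])
  } else {
    s$drug_events <- NA_character_
  }
  s$index_date <- format(s$index_date)
  out <- utils::capture.output(
    utils::write.table(s, sep = sep, quote = FALSE, row.names = FALSE, na = ""))
  if (is.null(file)) return(invisible(out))
  writeLines(out, file)
  invisible(file)
}

#' Apply subject exclusion rules
#'
#' Removes subjects matching the requested rules, logging each exclusion
#' with the rule that triggered it.  If a case is excluded its whole
#' stratum is dropped; if every control of a stratum is excluded the
#' stratum is dropped.  Built-in rules mirror a matched interview-based
#' case-control design: interviews rated completely unreliable
#' (reliability score 0), subjects flagged non-white (population
#' stratification control), and controls with a prior bleeding history.
#'
#' @param x a [cohort].
#' @param rules character vector among `"reliability_zero"`, `"non_white"`,
#'   `"control_prior_ugih"`.
#' @param extra named list of additional predicate functions
#'   `function(subjects) -> logical` marking subjects to exclude.
#' @return the filtered [cohort]; idempotent for a fixed rule set.
#' @export
apply_exclusions <- function(x,
                             rules = c("reliability_zero", "non_white",
                                       "control_prior_ugih"),
                             extra = list()) {
  s <- x$subjects
  preds <- list(
    reliability_zero = function(d) !is.na(d$reliability) & d$reliability == 0,
    non_white = function(d) !is.na(d$ancestry_flag) & d$ancestry_flag == "non-white",
    control_prior_ugih = function(d) d$is_case == 0 & !is.na(d$gi_history) &
      d$gi_history == "bleeding")
  preds <- c(preds[intersect(rules, names(preds))], extra)
  log <- x$exclusion_log
  out <- rep(FALSE, nrow(s))
  for (rule in names(preds)) {
    hit <- preds[[rule]](s)
    hit[is.na(hit)] <- FALSE
    new <- hit & !out
    if (any(new)) log <- rbind(log, data.frame(subject_id = s$subject_id[new],
                                               rule = rule))
    out <- out | hit
  }
  keep <- !out
  for (idx in split(seq_len(nrow(s)), s$stratum_id)) {
    alive <- idx[keep[idx]]
    ncase <- sum(s$is_case[alive]); nctl <- length(alive) - ncase
    if (length(alive) && (ncase != 1L || nctl < 1L)) {
      log <- rbind(log, data.frame(subject_id = s$subject_id[alive],
                                   rule = "stratum_dropped"))
      keep[idx] <- FALSE
    }
  }
  s <- s[keep, , drop = FALSE]
  rownames(s) <- NULL
  if (!nrow(s)) warning("all subjects excluded")
  ev <- x$drug_events[x$drug_events$subject_id %in% s$subject_id, , drop = FALSE]
  cohort(s, snp_catalog = x$snp_catalog, drug_events = ev, exclusion_log = log,
         validate = FALSE)
}

#' Dominant (carrier) coding of a genotype call
#'
#' Dichotomizes an allele-pair call against a biallelic SNP catalog entry:
#' 0 for the homozygous reference ("wild-type") genotype, 1 for carriage of
#' at least one variant allele ("genetic variation").  Missing calls
#' propagate as `NA`.  Allele order is irrelevant.
#'
#' @param call character vector of `"A/G"`-style calls (or `NA`).
#' @param ref,alt reference and variant allele of the SNP.
#' @param model `"dominant"` (carrier indicator) or `"codominant"`
#'   (variant-allele count 0/1/2).
#' @return integer vector, `NA` where the call is missing.
#' @export
code_dominant <- function(call, ref, alt, model = c("dominant", "codominant")) {
  model <- match.arg(model)
  out <- rep(NA_integer_, length(call))
  has <- !is.na(call) & nzchar(call)
  if (!any(has)) return(out)
  parts <- strsplit(call[has], "/", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed genotype call: ", call[has][lengths(parts) != 2L][1])
  }
  a1 <- vapply(parts, `[`, "", 1L); a2 <- vapply(parts, `[`, "", 2L)
  bad <- !(a1 %in% c(ref, alt)) | !(a2 %in% c(ref, alt))
  if (any(bad)) {
    stop("allele not in catalog (ref=", ref, ", alt=", alt, "): ",
         call[has][bad][1])
  }
  nvar <- (a1 == alt) + (a2 == alt)
  out[has] <- if (model == "dominant") as.integer(nvar > 0) else as.integer(nvar)
  out
}

#' Derive binary drug exposure from the event history
#'
#' A subject is exposed when at least one event of `drug_code` falls in the
#' closed etiological window `[index_date - window_days, index_date]`.
#' Events after the index date never count as exposure.
#'
#' @param x a [cohort].
#' @param drug_code drug code to look for (default `"ASA"`, aspirin).
#' @param window_days etiological window length in days (default 7).
#' @return data frame `subject_id`, `exposed` (0/1), `window_days`.
#' @export
derive_exposure <- function(x, drug_code = "ASA", window_days = 7) {
  stopifnot(window_days >= 1)
  s <- x$subjects
  if (anyNA(s$index_date)) {
    stop("missing index_date for subject ",
         s$subject_id[is.na(s$index_date)][1])
  }
  ev <- x$drug_events
  ev <- ev[ev$drug_code == drug_code, , drop = FALSE]
  exposed <- rep(0L, nrow(s))
  if (nrow(ev)) {
    idx <- match(ev$subject_id, s$subject_id)
    ok <- !is.na(idx)
    ev <- ev[ok, , drop = FALSE]; idx <- idx[ok]
    ind <- s$index_date[idx]
    inwin <- ev$date >= ind - window_days & ev$date <= ind
    exposed[unique(idx[inwin])] <- 1L
  }
  data.frame(subject_id = s$subject_id, exposed = exposed,
             window_days = window_days)
}
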