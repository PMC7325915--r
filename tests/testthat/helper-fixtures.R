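# Shared fixtures and independent oracles, built in code at test time.

# 8-row cohort table (2 strata of 1 case : 3 controls) as TSV lines
fixture_lines <- function(tweak = identity) {
  rows <- list(
    c("S1", "M1", "1", "C1", "P1", "64", "male", "normal", "2005-03-10", "8",
      "white", "patient", "1", "no", "yes", "none", "T/T", "ASA@2005-03-08"),
    c("S2", "M1", "0", "C1", "P1", "62", "male", "overweight", "2005-04-02", "9",
      "white", "patient", "1", "no", "no", "none", "T/C", ""),
    c("S3", "M1", "0", "C1", "P1", "66", "male", "obese", "2005-02-20", "7",
      "white", "proxy", "2", "yes", "yes", "ulcer", "T/T", "IBU@2005-02-01"),
    c("S4", "M1", "0", "C1", "P1", "63", "male", "normal", "2005-05-15", "10",
      "white", "patient", "1", "no", "yes", "none", "C/C", "ASA@2005-05-20"),
    c("S5", "M2", "1", "C2", "P2", "48", "female", "normal", "2014-06-01", "9",
      "white", "patient", "1", "no", "yes", "bleeding", "T/C", "ASA@2014-05-29"),
    c("S6", "M2", "0", "C2", "P2", "50", "female", "overweight", "2014-07-07", "8",
      "white", "patient", "1", "yes", "no", "none", "T/T", ""),
    c("S7", "M2", "0", "C2", "P2", "47", "female", "normal", "2014-08-11", "6",
      "white", "patient", "2", "no", "yes", "none", "T/T", "ASA@2014-07-20"),
    c("S8", "M2", "0", "C2", "P2", "52", "female", "obese", "2014-09-01", "9",
      "white", "proxy", "1", "no", "yes", "none", "T/C", ""))
  header <- c("subject_id", "stratum_id", "is_case", "center", "period", "age",
              "sex", "bmi_class", "index_date", "reliability", "ancestry_flag",
              "info_source", "n_interviews", "arthrosis", "h_pylori",
              "gi_history", "rs2238631", "drug_events")
  rows <- tweak(rows)
  vapply(c(list(header), rows), paste, "", collapse = "\t")
}

fixture_cohort <- function(...) read_cohort_table(fixture_lines(...))

fixture_catalog <- data.frame(snp_id = "rs2238631", ref = "T", alt = "C")

# small in-memory cohort built directly (no parsing involved)
toy_cohort <- function(n_strata = 3, controls = 3, seed = 1) {
  set.seed(seed)
  n <- n_strata * (controls + 1)
  subj <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    stratum_id = rep(sprintf("M%02d", seq_len(n_strata)), each = controls + 1),
    is_case = rep(c(1L, rep(0L, controls)), n_strata),
    center = rep("C1", n),
    age = sample(40:80, n, replace = TRUE),
    sex = "male",
    reliability = sample(5:10, n, replace = TRUE),
    ancestry_flag = "white",
    gi_history = "none",
    index_date = as.Date("2005-06-01"),
    rs0001 = sample(c("T/T", "T/C", "C/C"), n, replace = TRUE,
                    prob = c(0.5, 0.4, 0.1)),
    stringsAsFactors = FALSE)
  ev <- data.frame(subject_id = subj$subject_id[seq(1, n, by = 3)],
                   drug_code = "ASA",
                   date = as.Date("2005-05-30"))
  cohort(subj, snp_catalog = data.frame(snp_id = "rs0001", ref = "T", alt = "C"),
         drug_events = ev)
}

# random small matched design for likelihood tests
toy_design <- function(n_strata = 3, m = 3, p = 2, seed = 1, binary = TRUE) {
  set.seed(seed)
  n <- n_strata * (m + 1)
  X <- if (binary) {
    matrix(rbinom(n * p, 1, 0.4), n, p)
  } else {
    matrix(rnorm(n * p), n, p)
  }
  colnames(X) <- paste0("x", seq_len(p))
  structure(list(
    X = X, y = rep(c(1L, rep(0L, m)), n_strata),
    stratum = factor(rep(seq_len(n_strata), each = m + 1)),
    assign = seq_len(p), term_labels = colnames(X),
    n_obs = n, n_strata = n_strata,
    n_dropped_incomplete = 0L, n_strata_dropped = 0L,
    dropped_terms = character(0)), class = "matched_design")
}

# Independent oracle: conditional log-likelihood by plain-loop direct
# summation over which stratum member could be the case.
oracle_loglik <- function(beta, design) {
  total <- 0
  for (s in levels(design$stratum)) {
    idx <- which(design$stratum == s)
    case <- idx[design$y[idx] == 1L]
    num <- exp(sum(design$X[case, ] * beta))
    den <- 0
    for (j in idx) den <- den + exp(sum(design$X[j, ] * beta))
    total <- total + log(num / den)
  }
  total
}

# central finite-difference gradient of the oracle
oracle_gradient <- function(beta, design, h = 1e-6) {
  vapply(seq_along(beta), function(k) {
    e <- replace(numeric(length(beta)), k, h)
    (oracle_loglik(beta + e, design) - oracle_loglik(beta - e, design)) / (2 * h)
  }, 0)
}

# derivative-free maximizer of the oracle likelihood
oracle_mle <- function(design, start = NULL) {
  p <- ncol(design$X)
  start <- if (is.null(start)) numeric(p) else start
  if (p == 1L) {
    stats::optimize(function(b) oracle_loglik(b, design),
                    interval = c(-10, 10), maximum = TRUE,
                    tol = 1e-10)$maximum
  } else {
    stats::optim(start, function(b) -oracle_loglik(b, design),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$par
  }
}
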