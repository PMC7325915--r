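joint_fit <- function(n_strata = 400, seed = 17, ...) {
  sim <- simulate_cohort(sim_config(n_strata = n_strata, seed = seed, ...))
  d <- augment_cohort(sim$cohort, sim$truth$config$snp_id)
  fit <- fit_conditional_logistic(
    matched_design(d, ~ exp_only + carrier_only + both))
  list(fit = fit, data = d, truth = sim$truth)
}

test_that("joint recoding maps the four exposure-by-carrier combinations", {
  expect_equal(as.character(joint_recode(c(0, 1, 0, 1), c(0, 0, 1, 1))),
               c("ref", "exp_only", "carrier_only", "both"))
  expect_true(is.na(joint_recode(1, NA)))
  expect_error(joint_recode(2, 0), "binary")
})

test_that("RERI reproduces the published worked examples from printed ORs", {
  expect_equal(round(reri(8.22, 3.42, 0.85), 2), 4.95)
  expect_equal(round(reri(4.83, 3.26, 0.82), 2), 1.75)
  expect_equal(round(reri(3.09, 5.86, 0.97), 2), -2.74)
  expect_equal(reri(1, 1, 1), 0)
  expect_error(reri(-1, 2, 2), "positive")
})

test_that("synergism index reproduces worked examples and flags degeneracy", {
  expect_equal(round(synergy_index(8.22, 3.42, 0.85), 2), 3.18)
  expect_equal(round(synergy_index(4.03, 5.02, 0.96), 2), 0.76)
  expect_true(is.na(synergy_index(3.0, 1.5, 0.5)))      # excess odds cancel
  expect_warning(synergy_index(3.0, 0.5, 0.6), "negative")
  expect_error(synergy_index(2, 0, 1), "positive")
})

test_that("RERI from cell ORs equals RERI from model coefficients exactly", {
  jf <- joint_fit(n_strata = 250, seed = 23)
  ie <- interaction_ci(jf$fit)
  b <- coef(jf$fit)
  direct <- exp(b[["both"]]) - exp(b[["exp_only"]]) - exp(b[["carrier_only"]]) + 1
  so <- stratum_ors(jf$fit, mode = "joint-model", data = jf$data)
  ors <- setNames(so$cells$or, so$cells$cell)
  expect_equal(ie$reri, direct, tolerance = 1e-15)
  expect_equal(reri(ors[["both"]], ors[["exp_only"]], ors[["carrier_only"]]),
               direct, tolerance = 1e-12)
})

test_that("sign coherence: with positive summed excesses, RERI > 0 iff S > 1", {
  set.seed(5)
  for (i in 1:50) {
    or10 <- runif(1, 1.01, 6); or01 <- runif(1, 1.01, 6)
    or11 <- runif(1, 0.2, 12)
    r <- reri(or11, or10, or01)
    s <- synergy_index(or11, or10, or01)
    expect_equal(r > 0, s > 1)
  }
})

test_that("a multiplicative null still carries positive additive interaction", {
  set.seed(6)
  for (i in 1:20) {
    or10 <- runif(1, 1.1, 5); or01 <- runif(1, 1.1, 5)
    expect_equal(reri(or10 * or01, or10, or01), (or10 - 1) * (or01 - 1))
    expect_gt(reri(or10 * or01, or10, or01), 0)
  }
})

test_that("joint-model re-referencing is an exact coefficient contrast", {
  jf <- joint_fit(n_strata = 300, seed = 29)
  so <- stratum_ors(jf$fit, mode = "joint-model", data = jf$data)
  ors <- setNames(so$cells$or, so$cells$cell)
  rr <- setNames(so$rereferenced$or, so$rereferenced$contrast)
  expect_equal(rr[["exposure_in_carrier"]],
               ors[["both"]] / ors[["carrier_only"]], tolerance = 1e-12)
  expect_equal(rr[["carrier_in_exposed"]],
               ors[["both"]] / ors[["exp_only"]], tolerance = 1e-12)
  expect_equal(rr[["exposure_in_wildtype"]], ors[["exp_only"]],
               tolerance = 1e-12)
  # reference cell printed as exactly 1
  expect_equal(so$cells$or[so$cells$cell == "ref"], 1)
})

test_that("stratified-refit and joint-model modes agree on large cohorts", {
  jf <- joint_fit(n_strata = 1500, seed = 41, exposure_prev_controls = 0.15)
  jm <- stratum_ors(jf$fit, mode = "joint-model", data = jf$data)
  sr <- stratum_ors(jf$fit, mode = "stratified-refit", data = jf$data)
  for (ctr in c("exposure_in_wildtype", "exposure_in_carrier")) {
    a <- log(jm$rereferenced$or[jm$rereferenced$contrast == ctr])
    b <- log(sr$rereferenced$or[sr$rereferenced$contrast == ctr])
    ci <- log(c(jm$rereferenced$lower[jm$rereferenced$contrast == ctr],
                jm$rereferenced$upper[jm$rereferenced$contrast == ctr]))
    se <- diff(ci) / (2 * qnorm(0.975))
    expect_lt(abs(a - b), 3 * se)
  }
})

test_that("a degenerate zero covariance collapses the delta CI to a point", {
  fake <- structure(list(
    coefficients = c(exp_only = log(2), carrier_only = log(1.5), both = log(4)),
    vcov = matrix(0, 3, 3, dimnames = list(
      c("exp_only", "carrier_only", "both"),
      c("exp_only", "carrier_only", "both")))), class = "cond_fit")
  ie <- interaction_ci(fake, method = "delta")
  expect_equal(ie$reri_ci, rep(ie$reri, 2))
  expect_equal(ie$s_ci, rep(ie$s, 2))
})

test_that("the delta RERI interval covers zero near the nominal rate under
           the additive null", {
  covered <- vapply(1:120, function(i) {
    jf <- joint_fit(n_strata = 220, seed = 5000 + i, or10 = 1, or01 = 1,
                    target_reri = 0, exposure_prev_controls = 0.25)
    ie <- interaction_ci(jf$fit)
    ie$reri_ci[1] <= 0 && 0 <= ie$reri_ci[2]
  }, TRUE)
  # binomial 99.9% band around 0.95 at 120 replicates
  expect_lt(abs(mean(covered) - 0.95), 3.3 * sqrt(0.95 * 0.05 / 120))
})

test_that("bootstrap and delta intervals agree on a moderate cohort", {
  jf <- joint_fit(n_strata = 600, seed = 71, exposure_prev_controls = 0.2)
  del <- interaction_ci(jf$fit, method = "delta")
  boo <- interaction_ci(jf$fit, method = "bootstrap", n_boot = 400, seed = 1)
  width <- diff(del$reri_ci)
  expect_lt(abs(boo$reri_ci[1] - del$reri_ci[1]), 0.25 * width)
  expect_lt(abs(boo$reri_ci[2] - del$reri_ci[2]), 0.25 * width)
  # same seed reproduces the bootstrap exactly
  boo2 <- interaction_ci(jf$fit, method = "bootstrap", n_boot = 400, seed = 1)
  expect_identical(boo$reri_ci, boo2$reri_ci)
})

test_that("the S interval is reported undefined when S is non-positive while
           the RERI interval stands", {
  fake <- structure(list(
    coefficients = c(exp_only = log(3), carrier_only = log(2), both = log(0.8)),
    vcov = diag(0.04, 3) + 0.01), class = "cond_fit")
  dimnames(fake$vcov) <- list(c("exp_only", "carrier_only", "both"),
                              c("exp_only", "carrier_only", "both"))
  ie <- interaction_ci(fake, method = "delta")
  expect_true(all(is.na(ie$s_ci)))
  expect_true(all(is.finite(ie$reri_ci)))
})

test_that("sparse cells route a SNP to the inconclusive table", {
  jf <- joint_fit(n_strata = 300, seed = 83)
  so <- stratum_ors(jf$fit, mode = "joint-model", data = jf$data)
  ie <- interaction_ci(jf$fit)
  res_ok <- list(rs_ok = list(stratum_ors = so, interaction = ie))
  kt <- knol_table(res_ok)
  expect_equal(unique(kt$main$snp_id), "rs_ok")
  expect_equal(nrow(kt$inconclusive), 0L)

  so_sparse <- so
  so_sparse$cells$n_cases[so_sparse$cells$cell == "both"] <- 4L
  kt2 <- knol_table(list(rs_sparse = list(stratum_ors = so_sparse,
                                          interaction = ie)))
  expect_equal(nrow(kt2$main), 0L)
  expect_equal(unique(kt2$inconclusive$snp_id), "rs_sparse")

  # empty input gives valid empty tables with the full header
  kt0 <- knol_table(list())
  expect_equal(nrow(kt0$main), 0L)
  expect_true(all(c("snp_id", "cell", "reri", "s") %in% names(kt0$main)))
})
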