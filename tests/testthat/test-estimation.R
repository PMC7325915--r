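test_that("conditional log-likelihood at beta = 0 is uniform over the stratum", {
  des <- toy_design(n_strata = 1, m = 3, p = 2, seed = 2)
  ll <- conditional_loglik(c(0, 0), des)
  expect_equal(ll$value, log(1 / 4))
})

test_that("likelihood, gradient and Hessian match the direct-summation oracle", {
  for (seed in 1:4) {
    des <- toy_design(n_strata = 2, m = 3, p = 2, seed = seed)
    for (b1 in seq(-2, 2, by = 1)) for (b2 in c(-1.5, 0, 0.7)) {
      beta <- c(b1, b2)
      ll <- conditional_loglik(beta, des)
      expect_equal(ll$value, oracle_loglik(beta, des), tolerance = 1e-10)
      expect_equal(ll$gradient, oracle_gradient(beta, des),
                   tolerance = 1e-5, ignore_attr = TRUE)
    }
    # Hessian against finite differences of the analytic gradient
    beta <- c(0.3, -0.4); h <- 1e-6
    H_fd <- sapply(1:2, function(k) {
      e <- replace(numeric(2), k, h)
      (conditional_loglik(beta + e, des)$gradient -
         conditional_loglik(beta - e, des)$gradient) / (2 * h)
    })
    expect_equal(conditional_loglik(beta, des)$hessian, H_fd,
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("strata must contain exactly one case", {
  des <- toy_design(n_strata = 2, m = 2, seed = 1)
  des$y[1] <- 0L
  expect_error(conditional_loglik(c(0, 0), des), "exactly one case")
  des$y[c(1, 2)] <- 1L
  expect_error(conditional_loglik(c(0, 0), des), "exactly one case")
})

test_that("Newton fit agrees with a derivative-free oracle maximizer", {
  for (seed in c(3, 9, 14)) {
    des <- toy_design(n_strata = 3, m = 3, p = 2, seed = seed, binary = FALSE)
    fit <- fit_conditional_logistic(des)
    expect_true(fit$converged)
    expect_equal(unname(fit$coefficients), oracle_mle(des), tolerance = 1e-4)
    expect_gte(fit$loglik, oracle_loglik(oracle_mle(des), des) - 1e-8)
  }
})

test_that("the fit matches survival::clogit coefficient for coefficient", {
  library(survival)
  sim <- simulate_cohort(sim_config(n_strata = 200, seed = 31))
  d <- augment_cohort(sim$cohort, "rs689466")
  des <- matched_design(d, ~ exp_only + carrier_only + both + h_pylori)
  fit <- fit_conditional_logistic(des)
  cl <- clogit(
    is_case ~ exp_only + carrier_only + both + h_pylori + strata(stratum_id),
    data = d)
  expect_equal(unname(fit$coefficients), unname(coef(cl)), tolerance = 1e-7)
  expect_equal(unname(vcov(fit)), unname(vcov(cl)), tolerance = 1e-6)
  expect_equal(fit$loglik, cl$loglik[2], tolerance = 1e-8)
})

test_that("stratum-constant terms are absorbed by the matching", {
  sim <- simulate_cohort(sim_config(n_strata = 150, seed = 12))
  d <- augment_cohort(sim$cohort, "rs689466")
  base <- fit_conditional_logistic(matched_design(d, ~ exp_only + carrier_only + both))
  # center and period are constant within every matched set
  expect_message(
    des2 <- matched_design(d, ~ exp_only + carrier_only + both + center + period),
    "stratum-constant")
  with_const <- fit_conditional_logistic(des2)
  expect_equal(with_const$coefficients, base$coefficients, tolerance = 1e-9)
})

test_that("the fit is invariant to subject and stratum permutations", {
  des <- toy_design(n_strata = 5, m = 3, p = 2, seed = 8)
  fit <- fit_conditional_logistic(des)
  set.seed(42)
  perm <- sample(length(des$y))
  des2 <- des
  des2$X <- des$X[perm, , drop = FALSE]
  des2$y <- des$y[perm]
  des2$stratum <- des$stratum[perm]
  fit2 <- fit_conditional_logistic(des2)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-9)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-10)
})

test_that("vcov is symmetric positive semi-definite at the optimum", {
  for (seed in c(5, 6)) {
    des <- toy_design(n_strata = 8, m = 3, p = 3, seed = seed, binary = FALSE)
    fit <- fit_conditional_logistic(des)
    expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
    expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-10))
  }
})

test_that("null and non-null exposure effects are recovered from synthetic truth", {
  sim <- simulate_cohort(sim_config(n_strata = 1000, or10 = 1, or01 = 1,
                                    target_reri = 0, seed = 55,
                                    exposure_prev_controls = 0.15))
  d <- augment_cohort(sim$cohort, "rs689466")
  fit <- fit_conditional_logistic(matched_design(d, ~ exp_only + carrier_only + both))
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients) < 3 * se))

  sim2 <- simulate_cohort(sim_config(n_strata = 2500, or10 = 3, or01 = 1,
                                     target_reri = 0, maf = 0.3,
                                     exposure_prev_controls = 0.15, seed = 56))
  d2 <- augment_cohort(sim2$cohort, "rs689466")
  fit2 <- fit_conditional_logistic(matched_design(d2, ~ exposed))
  b <- fit2$coefficients["exposed"]
  se2 <- sqrt(fit2$vcov["exposed", "exposed"])
  expect_lt(abs(exp(b) - 3), 3 * se2 * exp(b))  # delta-method SE of the OR
})

test_that("complete separation is reported, not silently returned", {
  d <- data.frame(
    subject_id = as.character(1:12),
    stratum_id = rep(c("a", "b", "c"), each = 4),
    is_case = rep(c(1L, 0L, 0L, 0L), 3),
    x = rep(c(1, 0, 0, 0), 3))
  des <- matched_design(d, ~ x)
  expect_warning(fit <- fit_conditional_logistic(des), "separation")
  expect_true("x" %in% fit$separation)
})

test_that("crude odds ratio reproduces hand arithmetic and flags corrections", {
  # genetic-variation exposed cases/controls vs wild-type unexposed baseline
  res <- crude_or(14, 5, 143, 358)
  expect_equal(round(res$or, 2), 7.01)
  expect_false(res$corrected)
  expect_equal(crude_or(10, 10, 10, 10)$or, 1.0)
  zero <- crude_or(0, 5, 10, 20)
  expect_true(zero$corrected)
  expect_equal(zero$or, (0.5 * 20.5) / (5.5 * 10.5))
  expect_error(crude_or(0, 0, 10, 20), "undefined")
  expect_error(crude_or(1.5, 2, 3, 4), "integer")
})

test_that("screening keeps a constructed confounder and respects alpha = 1", {
  conf <- data.frame(name = "ppi_use", prevalence = 0.2,
                     or_outcome = 2.5, or_exposure = 2.0)
  sim <- simulate_cohort(sim_config(n_strata = 600, confounders = conf,
                                    exposure_prev_controls = 0.1, seed = 77))
  kept <- screen_covariates(sim$cohort, c("ppi_use", "h_pylori", "bmi_class"))
  expect_true("ppi_use" %in% kept)
  all_kept <- screen_covariates(sim$cohort, c("ppi_use", "h_pylori", "bmi_class"),
                                alpha = 1.0)
  expect_setequal(as.character(all_kept), c("ppi_use", "h_pylori", "bmi_class"))
  details <- attr(all_kept, "details")
  expect_equal(details$status, rep("ok", 3))
})

test_that("pure-noise covariates pass the screen at about the alpha rate", {
  set.seed(101)
  sim <- simulate_cohort(sim_config(n_strata = 150, or10 = 1, or01 = 1,
                                    target_reri = 0,
                                    exposure_prev_controls = 0.2, seed = 60))
  d <- augment_cohort(sim$cohort)
  hits <- vapply(1:250, function(i) {
    d$noise <- rnorm(nrow(d))
    length(screen_covariates(d, "noise", alpha = 0.2)) == 1L
  }, TRUE)
  # binomial 99.9% band around 0.2 at 250 replicates
  expect_lt(abs(mean(hits) - 0.2), 3.3 * sqrt(0.2 * 0.8 / 250))
})

test_that("backward elimination drops noise but keeps a real confounder", {
  conf <- data.frame(name = "ppi_use", prevalence = 0.25,
                     or_outcome = 3.5, or_exposure = 4.0)
  sim <- simulate_cohort(sim_config(n_strata = 800, confounders = conf,
                                    exposure_prev_controls = 0.08, seed = 78))
  d <- augment_cohort(sim$cohort, "rs689466")
  set.seed(1)
  d$noise1 <- rnorm(nrow(d))
  d$noise2 <- rbinom(nrow(d), 1, 0.5)
  des <- matched_design(d, ~ exp_only + carrier_only + both +
                          ppi_use + noise1 + noise2)
  res <- backward_eliminate(des, exposure_terms = c("exp_only", "carrier_only",
                                                    "both"),
                            candidates = c("ppi_use", "noise1", "noise2"))
  expect_true("ppi_use" %in% res$retained)
  expect_true(all(c("noise1", "noise2") %in% res$dropped))
  expect_true(all(res$log$action %in% c("dropped", "kept")))
})

test_that("cie = 0 only permits drops that leave exposure betas unchanged", {
  des <- toy_design(n_strata = 30, m = 3, p = 3, seed = 44, binary = FALSE)
  res <- backward_eliminate(des, exposure_terms = "x1",
                            candidates = c("x2", "x3"), cie = 0)
  expect_true(all(res$log$action[res$log$max_exposure_change > 0] == "kept"))
  for (cand in res$dropped) {
    expect_equal(res$log$max_exposure_change[res$log$candidate == cand &
                                               res$log$action == "dropped"], 0)
  }
})
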