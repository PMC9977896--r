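test_that("the slope implied by S inverts the asymptotic variance formula", {
  expect_equal(true_beta1(sim_scenario(100, 0)), 0)
  expect_equal(true_beta1(sim_scenario(100, 1)), 1 / sqrt(0.21))
  expect_equal(true_beta1(sim_scenario(100, 1, variance = "heteroskedastic")),
               sqrt(2.25 / 0.3 + 0.25 / 0.7))
})

test_that("oracle covariance matches closed forms", {
  expect_equal(oracle_covariance(sim_scenario(100, 1)), 1 / 0.21)
  expect_equal(oracle_covariance(sim_scenario(100, 1,
                                              variance = "heteroskedastic")),
               2.25 / 0.3 + 0.25 / 0.7)
  expect_equal(oracle_covariance(sim_scenario(100, 1, pi = 0.5)), 4)
})

test_that("the generator reproduces the stated covariate pattern and moments", {
  sc <- sim_scenario(50, 0.5, seed = 1)
  ds <- generate_dataset(sc)
  expect_equal(sum(ds$design[, "x"]), ceiling(50 * 0.3))  # exactly 15 ones

  # homoskedastic normal error variance ~ 1
  big <- generate_dataset(sim_scenario(1e5, 0, seed = 2))
  expect_equal(var(big$outcome), 1, tolerance = 0.02)
  expect_equal(mean(big$outcome), 0, tolerance = 0.02)

  # heteroskedastic shifted-gamma: group variances (x + 0.5)^2 = 0.25 / 2.25
  hg <- generate_dataset(sim_scenario(1e5, 0, error_family = "shifted_gamma",
                                      variance = "heteroskedastic", seed = 3))
  x <- hg$design[, "x"]
  expect_equal(var(hg$outcome[x == 0]), 0.25, tolerance = 0.03 * 0.25 / 0.25)
  expect_equal(var(hg$outcome[x == 1]), 2.25, tolerance = 0.03)
  expect_equal(mean(hg$outcome), 0, tolerance = 0.02)

  # random covariate mode draws Bernoulli(0.3)
  rd <- generate_dataset(sim_scenario(1e4, 0, covariate_mode = "random",
                                      seed = 4))
  expect_equal(mean(rd$design[, "x"]), 0.3, tolerance = 0.05)
})

test_that("skewness of the error families is as stated", {
  expect_equal(error_skewness(sim_scenario(50, 0)), 0)
  sc <- sim_scenario(50, 0, error_family = "shifted_gamma")
  expect_equal(error_skewness(sc), 2 / sqrt(0.1))
})

test_that("the robust estimator recovers S across scenario families", {
  set.seed(55)
  fams <- expand.grid(error_family = c("normal", "shifted_gamma"),
                      variance = c("homoskedastic", "heteroskedastic"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(fams))) {
    sc <- sim_scenario(10000, 0.66, error_family = fams$error_family[i],
                       variance = fams$variance[i])
    s_bar <- mean(replicate(150, {
      fit <- fit_ols(generate_dataset(sc))
      V <- coef_covariance(fit, "robust")
      resi_point(wald_statistic(fit$theta_hat[2], V[2, 2, drop = FALSE],
                                n = fit$n, m = 2))
    }))
    expect_equal(s_bar, 0.66, tolerance = 0.03)
  }
})

test_that("run_study returns a tidy, reproducible coverage report", {
  sc <- sim_scenario(50, 0.33)
  r1 <- run_study(sc, estimators = c("oracle", "robust"),
                  interval_methods = c("chisq", "f"), n_sims = 50, seed = 12)
  expect_s3_class(r1, "resi_coverage_report")
  expect_equal(nrow(r1), 4)
  expect_true(all(c("n", "S", "estimator", "method", "coverage", "mean_bias",
                    "mc_se", "n_sims", "complete") %in% names(r1)))
  expect_true(all(r1$coverage >= 0 & r1$coverage <= 1))
  expect_true(all(r1$complete))
  expect_equal(r1$mc_se, sqrt(r1$coverage * (1 - r1$coverage) / r1$n_sims))

  r2 <- run_study(sc, estimators = c("oracle", "robust"),
                  interval_methods = c("chisq", "f"), n_sims = 50, seed = 12)
  expect_identical(r1$coverage, r2$coverage)
  r3 <- run_study(sc, estimators = c("oracle", "robust"),
                  interval_methods = c("chisq", "f"), n_sims = 50, seed = 13)
  expect_false(identical(r1$coverage, r3$coverage))
})

test_that("statistic variances order as oracle < parametric < robust at large S", {
  set.seed(99)
  sc <- sim_scenario(500, 1)
  n_rep <- 1500
  t2 <- matrix(NA_real_, n_rep, 3,
               dimnames = list(NULL, c("oracle", "parametric", "robust")))
  ov <- oracle_covariance(sc)
  for (i in seq_len(n_rep)) {
    fit <- fit_ols(generate_dataset(sc))
    b <- fit$theta_hat[2]
    t2[i, "oracle"] <- b^2 * fit$n / ov
    t2[i, "parametric"] <- b^2 / coef_covariance(fit, "parametric")[2, 2]
    t2[i, "robust"] <- b^2 / coef_covariance(fit, "robust")[2, 2]
  }
  v <- apply(t2, 2, var)
  expect_lt(v["oracle"], v["parametric"])
  expect_lt(v["parametric"], v["robust"])
})
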