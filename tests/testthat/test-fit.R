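test_that("OLS solves the normal equations and recovers exact structure", {
  # exact interpolation: no noise, coefficients recovered exactly
  X <- cbind(`(Intercept)` = 1, x1 = c(1, 2, 3, 4, 5), x2 = c(0, 1, 0, 1, 1))
  cf <- c(1, -0.5, 2)
  fit <- fit_ols(resi_dataset(drop(X %*% cf), X))
  expect_equal(unname(fit$theta_hat), cf, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 5), tolerance = 1e-12)

  # intercept-only: sample mean and variance
  fit2 <- fit_ols(resi_dataset(c(1, 2, 3), cbind(`(Intercept)` = rep(1, 3))))
  expect_equal(unname(fit2$theta_hat), 2)
  expect_equal(fit2$sigma2_hat, 1)

  # independent optimizer oracle on a random dataset
  ds <- make_lm_dataset(n = 20, m = 3, seed = 4)
  fit3 <- fit_ols(ds)
  sse <- function(th) sum((ds$outcome - ds$design %*% th)^2)
  opt <- optim(rep(0, 3), sse, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(fit3$theta_hat), opt$par, tolerance = 1e-6)
})

test_that("OLS leverages behave like a projection diagonal", {
  ds <- make_lm_dataset(n = 30, m = 4, seed = 2)
  fit <- fit_ols(ds)
  expect_equal(sum(fit$hat_values), fit$m, tolerance = 1e-10)
  expect_true(all(fit$hat_values > 0 & fit$hat_values < 1))
  expect_equal(fit$J_hat, t(fit$J_hat))
  expect_equal(fit$K_hat, t(fit$K_hat))
})

test_that("rank-deficient designs raise a catchable rank error", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))  # third column = 2 * second
  expect_error(fit_ols(resi_dataset(rnorm(4), X)),
               class = "resi_rank_deficiency")
  # effective rank deficiency after zero-weight removal
  Xf <- cbind(`(Intercept)` = 1, x = c(1, 1, 1, 0, 0))
  ds <- resi_dataset(rnorm(5), Xf, case_weights = c(1, 1, 1, 0, 0))
  expect_error(fit_ols_weighted(ds), class = "resi_rank_deficiency")
})

test_that("weighted least squares respects weight invariances", {
  ds <- make_lm_dataset(n = 25, m = 3, seed = 7)
  unweighted <- fit_ols(ds)

  ds1 <- resi_dataset(ds$outcome, ds$design, rep(1, 25))
  expect_equal(fit_ols_weighted(ds1)$theta_hat, unweighted$theta_hat,
               tolerance = 1e-10)

  ds2 <- resi_dataset(ds$outcome, ds$design, rep(2, 25))
  expect_equal(fit_ols_weighted(ds2)$theta_hat, unweighted$theta_hat,
               tolerance = 1e-10)

  # integer weights reproduce the fit on row-replicated data
  set.seed(11)
  w <- sample(1:3, 25, replace = TRUE)
  dsw <- resi_dataset(ds$outcome, ds$design, w)
  rep_idx <- rep(seq_len(25), times = w)
  dsr <- resi_dataset(ds$outcome[rep_idx], ds$design[rep_idx, ])
  fw <- fit_ols_weighted(dsw)
  fr <- fit_ols(dsr)
  expect_equal(fw$theta_hat, fr$theta_hat, tolerance = 1e-10)
  expect_equal(fw$J_hat * fw$n, fr$J_hat * fr$n, tolerance = 1e-10)
  expect_equal(fw$K_hat * fw$n, fr$K_hat * fr$n, tolerance = 1e-10)
})

test_that("logistic fit matches closed forms and is stationary", {
  # intercept-only: logit of the outcome mean
  y <- c(rep(1, 3), rep(0, 7))
  fit <- fit_logistic(resi_dataset(y, cbind(`(Intercept)` = rep(1, 10))))
  expect_equal(unname(fit$theta_hat), log(0.3 / 0.7), tolerance = 1e-8)

  # binary covariate: slope equals the log odds ratio of the 2x2 table
  set.seed(21)
  x <- rbinom(50, 1, 0.5)
  p <- plogis(-0.5 + 1.2 * x)
  yb <- rbinom(50, 1, p)
  tab <- table(factor(x, 0:1), factor(yb, 0:1))
  lor <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  fitb <- fit_logistic(resi_dataset(yb, cbind(`(Intercept)` = 1, x = x)))
  expect_equal(unname(fitb$theta_hat[2]), lor, tolerance = 1e-6)

  # score vector vanishes at the estimate
  score <- crossprod(fitb$data$design, yb - fitb$fitted_mu) / fitb$n
  expect_lt(sqrt(sum(score^2)), 1e-8)
})

test_that("complete separation raises a convergence error", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x  # perfectly separated
  expect_error(fit_logistic(resi_dataset(y, cbind(`(Intercept)` = 1, x = x))),
               class = "resi_convergence_error")
})

test_that("logistic outcomes must be coded 0/1", {
  expect_error(fit_logistic(resi_dataset(c(0, 1, 2),
                                         cbind(`(Intercept)` = rep(1, 3)))),
               class = "resi_input_error")
})
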