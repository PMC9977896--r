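# Model fitting: linear (ordinary and weighted least squares) and logistic
# (IRLS) fits, each returning the ingredients every downstream statistic
# needs: coefficient vector, residuals, leverages, the estimating-equation
# curvature and score-outer-product matrices J and K, and (for linear models)
# the usual residual variance estimate.
#
# Scale convention used throughout the package: J and K are per-observation
# averages, so J^{-1} K J^{-1} estimates the covariance of sqrt(n)*(theta_hat
# - theta); all *stored covariance matrices* returned by coef_covariance()
# and sandwich_covariance() are for theta_hat itself (i.e. divided by n).

# Weighted least-squares kernel. w = NULL means unit weights (fast path used
# heavily by the bootstrap layer).
.ls_fit <- function(y, X, w = NULL) {
  n <- length(y)
  m <- ncol(X)
  if (n <= m) {
    resi_error("need n > m observations for variance estimation",
               "resi_input_error")
  }
  if (is.null(w)) {
    XtX <- crossprod(X)
    Xty <- crossprod(X, y)
  } else {
    XtX <- crossprod(X, X * w)
    Xty <- crossprod(X, w * y)
  }
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R) ||
      any(diag(R)^2 <= max(diag(XtX)) * .Machine$double.eps * m * 4)) {
    resi_error("design matrix is rank deficient (after zero-weight removal)",
               "resi_rank_deficiency")
  }
  XtXinv <- chol2inv(R)
  theta <- drop(XtXinv %*% Xty)
  e <- y - drop(X %*% theta)
  h <- rowSums((X %*% XtXinv) * X)
  if (!is.null(w)) h <- h * w
  list(theta = theta, residuals = e, hat = h, XtXinv = XtXinv, XtX = XtX,
       n = n, m = m)
}

.new_fit <- function(kernel, X, w, family, data, extras = list()) {
  theta <- kernel$theta
  names(theta) <- colnames(X)
  out <- c(list(theta_hat = theta,
                beta_index = seq_len(kernel$m)[-1],
                residuals = kernel$residuals,
                hat_values = kernel$hat,
                xtx_inv = kernel$XtXinv,
                n = kernel$n, m = kernel$m,
                family = family,
                weights = w,
                data = data),
           extras)
  out$m1 <- length(out$beta_index)
  class(out) <- "resi_fit"
  out
}

#' Fit a linear model by ordinary least squares
#'
#' @param data A \code{\link{resi_dataset}}. Case weights in \code{data} are
#'   ignored here; use \code{\link{fit_ols_weighted}} for weighted fits.
#'
#' @return An object of class \code{resi_fit} with elements
#'   \code{theta_hat}, \code{beta_index} (non-intercept coefficients by
#'   default), \code{residuals}, \code{hat_values}, \code{J_hat},
#'   \code{K_hat}, \code{sigma2_hat}, \code{n}, \code{m}, \code{m1}.
#'   \code{J_hat} and \code{K_hat} are on the per-observation scale, so the
#'   sandwich \code{J_hat^-1 K_hat J_hat^-1 / n} estimates the covariance of
#'   the coefficient vector.
#' @export
fit_ols <- function(data) {
  stopifnot(inherits(data, "resi_dataset"))
  X <- data$design
  k <- .ls_fit(data$outcome, X)
  sigma2 <- sum(k$residuals^2) / (k$n - k$m)
  fit <- .new_fit(k, X, w = NULL, family = "gaussian", data = data,
                  extras = list(J_hat = k$XtX / k$n,
                                K_hat = crossprod(X * k$residuals) / k$n,
                                sigma2_hat = sigma2))
  fit
}

#' Fit a linear model by weighted least squares
#'
#' Minimizes the weighted residual sum of squares using the case weights
#' stored in \code{data}. With all weights equal the result coincides with
#' \code{\link{fit_ols}}; integer weights reproduce a fit on row-replicated
#' data. Rows with zero weight do not enter the normal equations (their
#' leverage is reported as 0).
#'
#' @inheritParams fit_ols
#' @return A \code{resi_fit}; see \code{\link{fit_ols}}.
#' @export
fit_ols_weighted <- function(data) {
  stopifnot(inherits(data, "resi_dataset"))
  X <- data$design
  w <- data$case_weights
  k <- .ls_fit(data$outcome, X, w)
  sigma2 <- sum(w * k$residuals^2) / (k$n - k$m)
  # Case weights are frequency weights: an observation with weight w
  # contributes w copies of its score to K (linear in w), exactly as a
  # multinomially resampled row would. This keeps the weighted sandwich the
  # plug-in of the sandwich functional at the weighted empirical
  # distribution, which is what the Bayesian bootstrap requires.
  .new_fit(k, X, w = w, family = "gaussian", data = data,
           extras = list(J_hat = k$XtX / k$n,
                         K_hat = crossprod(X * (sqrt(w) * k$residuals)) / k$n,
                         sigma2_hat = sigma2))
}

#' Fit a logistic regression model
#'
#' Maximizes the (case-weighted) Bernoulli log-likelihood by iteratively
#' reweighted least squares. \code{J_hat} is the expected information at the
#' estimate and \code{K_hat} the average outer product of per-observation
#' scores; they coincide asymptotically when the model is correct.
#'
#' @inheritParams fit_ols
#' @param max_iter Maximum IRLS iterations before declaring non-convergence.
#'
#' @return A \code{resi_fit}; \code{sigma2_hat} is \code{NULL} for logistic
#'   fits. \code{residuals} are response residuals \code{y - mu}.
#' @export
fit_logistic <- function(data, max_iter = 50L) {
  stopifnot(inherits(data, "resi_dataset"))
  y <- data$outcome
  if (!all(y %in% c(0, 1))) {
    resi_error("logistic outcome must be coded 0/1", "resi_input_error")
  }
  X <- data$design
  w <- data$case_weights
  n <- length(y)
  # glm.fit's binomial initializer warns on non-integer case weights (the
  # Bayesian bootstrap uses Dirichlet weights); that warning is expected.
  g <- withCallingHandlers(
    stats::glm.fit(X, y, weights = w, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = max_iter)),
    warning = function(cnd) {
      # non-integer weights are expected (Bayesian bootstrap); probabilities
      # pinned at 0/1 are re-diagnosed as separation below
      if (grepl("non-integer|numerically 0 or 1", conditionMessage(cnd))) {
        invokeRestart("muffleWarning")
      }
    })
  theta <- g$coefficients
  if (anyNA(theta) || g$rank < ncol(X)) {
    resi_error("design matrix is rank deficient in logistic fit",
               "resi_rank_deficiency")
  }
  mu <- g$fitted.values
  score <- crossprod(X, w * (y - mu)) / n
  if (!g$converged || max(abs(theta)) > 30) {
    resi_error(paste0("logistic fit did not converge (possible separation): ",
                      g$iter, " iterations, max|coef| = ",
                      signif(max(abs(theta)), 4), ", |score| = ",
                      signif(sqrt(sum(score^2)), 4)),
               "resi_convergence_error")
  }
  v <- w * mu * (1 - mu)
  XtWVX <- crossprod(X, X * v)
  Rv <- tryCatch(chol(XtWVX), error = function(e) NULL)
  if (is.null(Rv)) {
    resi_error("information matrix singular in logistic fit",
               "resi_rank_deficiency")
  }
  info_inv <- chol2inv(Rv)
  kernel <- list(theta = theta, residuals = y - mu,
                 hat = rowSums((X %*% info_inv) * X) * v,
                 XtXinv = info_inv, XtX = XtWVX, n = n, m = ncol(X))
  .new_fit(kernel, X, w = w, family = "binomial", data = data,
           extras = list(J_hat = XtWVX / n,
                         K_hat = crossprod(X * (sqrt(w) * (y - mu))) / n,
                         sigma2_hat = NULL,
                         fitted_mu = mu, iterations = g$iter))
}

#' @export
print.resi_fit <- function(x, ...) {
  cat("<resi_fit> family =", x$family, " n =", x$n, " m =", x$m, "\n")
  print(x$theta_hat)
  invisible(x)
}
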