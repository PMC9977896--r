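# The Wald statistic and the RESI point estimator.

#' Wald statistic for a coefficient block
#'
#' Computes \eqn{T^2 = (\hat\beta - \beta_0)' \widehat{Cov}(\hat\beta)^{-1}
#' (\hat\beta - \beta_0)} for a block of target coefficients. Because the
#' covariance passed in is that of \eqn{\hat\beta} itself (already on the
#' 1/n scale), the statistic carries its usual n-scaling implicitly. Under
#' the alternative the oracle version is non-central chi-squared with
#' noncentrality \eqn{n S^2}.
#'
#' @param beta_hat Estimated target coefficients (length m1).
#' @param cov_beta_hat Covariance matrix of \code{beta_hat} (m1 x m1). It is
#'   symmetrized as \code{(A + t(A))/2} before inversion.
#' @param beta0 Reference value; defaults to the zero vector.
#' @param n Sample size (bookkeeping for downstream RESI computation).
#' @param flavor Label recorded on the result: \code{"oracle"},
#'   \code{"parametric"} or \code{"robust"}.
#' @param allow_pseudoinverse If \code{TRUE}, a singular covariance is
#'   inverted with the Moore–Penrose pseudoinverse instead of failing. Off by
#'   default: a singular covariance usually signals a misspecified block.
#'
#' @return An object of class \code{resi_wald}: list with \code{t2},
#'   \code{flavor}, \code{m1}, \code{n}, \code{m}, \code{beta0}.
#' @export
wald_statistic <- function(beta_hat, cov_beta_hat, beta0 = NULL, n,
                           flavor = c("robust", "parametric", "oracle"),
                           m = length(beta_hat), allow_pseudoinverse = FALSE) {
  flavor <- match.arg(flavor)
  beta_hat <- as.numeric(beta_hat)
  m1 <- length(beta_hat)
  if (is.null(beta0)) beta0 <- numeric(m1)
  stopifnot(length(beta0) == m1, n > 0)
  V <- as.matrix(cov_beta_hat)
  V <- (V + t(V)) / 2
  d <- beta_hat - beta0
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(R)) {
    z <- backsolve(R, d, transpose = TRUE)
    t2 <- sum(z^2)
  } else if (allow_pseudoinverse) {
    t2 <- drop(crossprod(d, MASS::ginv(V) %*% d))
  } else {
    resi_error("covariance matrix is not positive definite",
               "resi_singular_covariance")
  }
  structure(list(t2 = t2, flavor = flavor, m1 = m1, n = as.integer(n),
                 m = as.integer(m), beta0 = beta0),
            class = "resi_wald")
}

#' RESI point estimate from a Wald statistic
#'
#' The consistent estimator \eqn{\hat S = \sqrt{\max(0, (T^2 - m_1)/n)}}:
#' the observed statistic is equated to the mean of the non-central
#' chi-squared distribution, solved for the effect size, and truncated at
#' zero (the estimand is nonnegative).
#'
#' @param t2 Wald statistic (scalar or vector), or a \code{resi_wald}
#'   object, in which case \code{m1} and \code{n} are taken from it.
#' @param m1 Degrees of freedom of the target block.
#' @param n Sample size.
#'
#' @return Nonnegative estimate(s) of the RESI.
#' @export
resi_point <- function(t2, m1, n) {
  if (inherits(t2, "resi_wald")) {
    m1 <- t2$m1
    n <- t2$n
    t2 <- t2$t2
  }
  stopifnot(all(t2 >= 0), n > 0, m1 >= 1)
  sqrt(pmax(0, (t2 - m1) / n))
}
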