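# Confidence intervals for the noncentrality parameter (NCP) of non-central
# chi-squared and F distributions by CDF inversion, and the mapping from NCP
# scale to RESI scale. The CDF of either family is strictly decreasing in
# the NCP, so each bound is the root of a monotone scalar equation and plain
# bisection is guaranteed to converge.

# Solve cdf(lambda) = target for lambda on [0, cap]; cdf strictly decreasing.
# Returns 0 (with truncated = TRUE) when even lambda = 0 lies below target.
.invert_ncp <- function(cdf, target, t2_obs, tol = 1e-8) {
  if (cdf(0) <= target) {
    return(list(value = 0, truncated = TRUE))
  }
  cap <- t2_obs + 100 * sqrt(t2_obs) + 1000
  hi <- max(t2_obs, 1)
  while (cdf(hi) > target) {
    hi <- hi * 2
    if (hi > cap) {
      if (cdf(cap) > target) {
        resi_error("NCP bracket expansion exceeded its cap; statistic too large",
                   "resi_bracket_failure")
      }
      hi <- cap
      break
    }
  }
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- cdf(mid)
    if (abs(fm - target) < tol) {
      return(list(value = mid, truncated = FALSE))
    }
    if (fm > target) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * (1 + hi)) break
  }
  list(value = (lo + hi) / 2, truncated = FALSE)
}

.new_ncp_interval <- function(lower, upper, family, dof1, dof2, level) {
  structure(list(lower = lower$value, upper = upper$value, family = family,
                 dof1 = as.integer(dof1),
                 dof2 = if (is.null(dof2)) NULL else as.integer(dof2),
                 level = level,
                 lower_truncated = lower$truncated,
                 upper_truncated = upper$truncated),
            class = "resi_ncp_interval")
}

#' NCP confidence interval from a non-central chi-squared statistic
#'
#' Inverts the non-central chi-squared CDF at the observed statistic: the
#' lower bound solves \eqn{F(t^2_{obs}; m_1, \lambda) = 1 - \alpha/2}, the
#' upper bound solves \eqn{F(t^2_{obs}; m_1, \lambda) = \alpha/2}. When no
#' root exists in \eqn{[0, \infty)} the bound is truncated at 0 and flagged
#' (never returned as missing).
#'
#' @param t2_obs Observed Wald statistic (nonnegative).
#' @param m1 Degrees of freedom of the statistic.
#' @param alpha One minus the confidence level (0.05 gives a 95\% CI).
#'
#' @return A \code{resi_ncp_interval}: list with \code{lower}, \code{upper},
#'   \code{family}, \code{dof1}, \code{dof2} (NULL here), \code{level}, and
#'   truncation flags \code{lower_truncated}, \code{upper_truncated}.
#' @export
chisq_ncp_ci <- function(t2_obs, m1, alpha = 0.05) {
  stopifnot(t2_obs >= 0, m1 >= 1, alpha > 0, alpha < 1)
  cdf <- function(lambda) stats::pchisq(t2_obs, df = m1, ncp = lambda)
  lower <- .invert_ncp(cdf, 1 - alpha / 2, t2_obs)
  upper <- .invert_ncp(cdf, alpha / 2, t2_obs)
  .new_ncp_interval(lower, upper, "chisq", m1, NULL, 1 - alpha)
}

#' NCP confidence interval from a non-central F statistic
#'
#' As \code{\link{chisq_ncp_ci}} but for the F distribution with
#' \code{m1} and \code{dof2} degrees of freedom. The observed Wald statistic
#' is divided by \code{m1} before being passed to the F CDF, matching the
#' distributional result \eqn{T^2_{(p)}/m_1 \sim F(m_1, n-m; nS^2)} for
#' linear models. For large \code{dof2} the bounds converge to the
#' chi-squared ones.
#'
#' @inheritParams chisq_ncp_ci
#' @param dof2 Denominator degrees of freedom, usually \code{n - m}.
#' @return A \code{resi_ncp_interval} with \code{family = "f"}.
#' @export
f_ncp_ci <- function(t2_obs, m1, dof2, alpha = 0.05) {
  stopifnot(t2_obs >= 0, m1 >= 1, dof2 >= 1, alpha > 0, alpha < 1)
  fstat <- t2_obs / m1
  cdf <- function(lambda) stats::pf(fstat, df1 = m1, df2 = dof2, ncp = lambda)
  lower <- .invert_ncp(cdf, 1 - alpha / 2, t2_obs)
  upper <- .invert_ncp(cdf, alpha / 2, t2_obs)
  .new_ncp_interval(lower, upper, "f", m1, dof2, 1 - alpha)
}

#' Convert an NCP interval to the RESI scale
#'
#' The squared RESI is the NCP divided by the sample size, so bounds map by
#' \eqn{\lambda \mapsto \sqrt{\lambda / n}}.
#'
#' @param iv A \code{resi_ncp_interval}.
#' @param n Sample size.
#' @return Numeric vector \code{c(lower, upper)} on the RESI scale.
#' @export
ncp_interval_to_resi <- function(iv, n) {
  stopifnot(inherits(iv, "resi_ncp_interval"), n > 0)
  c(sqrt(iv$lower / n), sqrt(iv$upper / n))
}

#' @export
print.resi_ncp_interval <- function(x, ...) {
  cat(sprintf("<resi_ncp_interval> %s(%d%s) %.0f%%: [%.6g, %.6g]%s\n",
              x$family, x$dof1,
              if (is.null(x$dof2)) "" else paste0(", ", x$dof2),
              100 * x$level, x$lower, x$upper,
              if (x$lower_truncated || x$upper_truncated)
                " (truncated at 0)" else ""))
  invisible(x)
}
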