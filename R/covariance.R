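# Covariance estimators for the fitted coefficient vector. Everything here
# returns the covariance of theta_hat (not of sqrt(n) theta_hat); the Wald
# layer therefore needs no extra n factor.

#' Heteroskedasticity-consistent (sandwich) covariance of the coefficients
#'
#' Two flavors are available. \code{"linear_hc3"} is the jackknife-type HC3
#' estimator for least-squares fits,
#' \deqn{(X'WX)^{-1} \left[\sum_i w_i^2 e_i^2 (1-h_i)^{-2} x_i x_i'\right] (X'WX)^{-1},}
#' which inflates each squared residual by its leverage. \code{"score_sandwich"}
#' is the general M-estimation sandwich \eqn{J^{-1} K J^{-1} / n} built from
#' the per-observation score outer products; it is the flavor used for
#' logistic models, where HC3 is not defined.
#'
#' @param model A \code{resi_fit}.
#' @param flavor \code{"linear_hc3"} (least-squares fits only) or
#'   \code{"score_sandwich"}.
#'
#' @return An m x m covariance matrix for \code{theta_hat}.
#' @export
sandwich_covariance <- function(model,
                                flavor = c("linear_hc3", "score_sandwich")) {
  stopifnot(inherits(model, "resi_fit"))
  flavor <- match.arg(flavor)
  if (flavor == "score_sandwich") {
    Jinv <- solve(model$J_hat)
    return((Jinv %*% model$K_hat %*% Jinv) / model$n)
  }
  if (model$family != "gaussian") {
    resi_error("linear_hc3 is defined for least-squares fits only",
               "resi_input_error")
  }
  h <- model$hat_values
  if (any(h >= 1 - 1e-12)) {
    resi_error("a leverage value equals 1; HC3 weights are degenerate",
               "resi_degenerate_leverage")
  }
  # Frequency-weight convention: each squared residual enters once per unit
  # of case weight (linear in w), so a weighted fit matches the sandwich of
  # the corresponding row-replicated data.
  w <- if (is.null(model$weights)) rep(1, model$n) else model$weights
  u <- sqrt(w) * model$residuals / (1 - h)
  meat <- crossprod(model$data$design * u)
  model$xtx_inv %*% meat %*% model$xtx_inv
}

#' Coefficient covariance under a named flavor
#'
#' Convenience dispatcher used by the Wald/bootstrap/table layers.
#' \code{"parametric"} is the model-based covariance (\eqn{\hat\sigma^2
#' (X'WX)^{-1}} for linear fits, inverse expected information for logistic
#' fits); \code{"robust"} is \code{\link{sandwich_covariance}} with the
#' model-appropriate flavor (HC3 for linear, score sandwich for logistic);
#' \code{"oracle"} divides a supplied true covariance of
#' \eqn{\sqrt{n}(\hat\theta - \theta)} by n.
#'
#' @param model A \code{resi_fit}.
#' @param flavor One of \code{"parametric"}, \code{"robust"},
#'   \code{"oracle"}.
#' @param oracle For \code{flavor = "oracle"}: the known asymptotic
#'   covariance matrix of \code{sqrt(n) * (theta_hat - theta)} (an m x m
#'   matrix, or a scalar/submatrix matching \code{model$beta_index} — in that
#'   case only the target block is returned).
#'
#' @return Covariance matrix for \code{theta_hat} (or its target block when a
#'   block-sized oracle is supplied).
#' @export
coef_covariance <- function(model, flavor = c("robust", "parametric", "oracle"),
                            oracle = NULL) {
  stopifnot(inherits(model, "resi_fit"))
  flavor <- match.arg(flavor)
  switch(flavor,
    parametric = if (model$family == "gaussian") {
      model$sigma2_hat * model$xtx_inv
    } else {
      model$xtx_inv  # inverse expected information = J_hat^{-1}/n
    },
    robust = sandwich_covariance(
      model,
      if (model$family == "gaussian") "linear_hc3" else "score_sandwich"),
    oracle = {
      if (is.null(oracle)) {
        resi_error("flavor 'oracle' needs the true covariance matrix",
                   "resi_input_error")
      }
      as.matrix(oracle) / model$n
    })
}
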