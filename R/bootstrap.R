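# Resampling intervals for the RESI: nonparametric percentile bootstrap CIs
# and Bayesian-bootstrap credible intervals. The resampling unit is always
# the full row (outcome + covariates), so the intervals remain valid when
# the design is random. One master seed drives per-replicate substreams so
# results do not depend on execution order.

# RESI point estimates for one or more coefficient blocks of a fit.
.s_hat_blocks <- function(fit, blocks, flavor, oracle_cov = NULL) {
  if (flavor == "oracle") {
    if (length(blocks) != 1L || is.null(oracle_cov)) {
      resi_error("oracle flavor needs a single block and its true covariance",
                 "resi_input_error")
    }
    covb <- as.matrix(oracle_cov) / fit$n
    b <- blocks[[1L]]
    w <- wald_statistic(fit$theta_hat[b], covb, n = fit$n, flavor = "oracle",
                        m = fit$m)
    return(resi_point(w))
  }
  V <- coef_covariance(fit, flavor)
  vapply(blocks, function(b) {
    w <- wald_statistic(fit$theta_hat[b], V[b, b, drop = FALSE], n = fit$n,
                        flavor = flavor, m = fit$m)
    resi_point(w)
  }, numeric(1))
}

# Empirical percentile interval: order statistics at ceil(R*alpha/2) and
# ceil(R*(1-alpha/2)), ties kept.
.percentile_interval <- function(reps, alpha) {
  reps <- reps[!is.na(reps)]
  R <- length(reps)
  s <- sort(reps)
  c(s[max(1L, ceiling(R * alpha / 2))], s[ceiling(R * (1 - alpha / 2))])
}

.refit <- function(model, ds) {
  if (model == "logistic") {
    fit_logistic(ds)
  } else if (any(ds$case_weights != 1)) {
    fit_ols_weighted(ds)
  } else {
    fit_ols(ds)
  }
}

# Shared engine. blocks: list of coefficient index vectors; returns the
# R x length(blocks) matrix of replicate RESI estimates plus bookkeeping.
.resi_boot <- function(data, model = "linear", flavor = "robust", blocks,
                       R = 1000L, alpha = 0.05, seed = NULL,
                       type = c("nonparam", "bayes"), oracle_cov = NULL,
                       weight_sampler = NULL) {
  type <- match.arg(type)
  stopifnot(R >= 2)
  n <- length(data$outcome)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(2147483646L, R)
  reps <- matrix(NA_real_, R, length(blocks))
  n_failed <- 0L
  catch <- function(expr) {
    tryCatch(expr,
             resi_rank_deficiency = function(e) NULL,
             resi_convergence_error = function(e) NULL)
  }
  for (r in seq_len(R)) {
    set.seed(rep_seeds[r])
    fit <- NULL
    if (type == "nonparam") {
      for (attempt in 1:10) {  # redraw degenerate resamples, then give up
        idx <- sample.int(n, n, replace = TRUE)
        ds <- structure(list(outcome = data$outcome[idx],
                             design = data$design[idx, , drop = FALSE],
                             case_weights = data$case_weights[idx]),
                        class = "resi_dataset")
        fit <- catch(.refit(model, ds))
        if (!is.null(fit)) break
      }
    } else {
      g <- if (is.null(weight_sampler)) {
        gg <- stats::rexp(n)
        gg / sum(gg)
      } else {
        weight_sampler(n)
      }
      if (abs(sum(g) - 1) > 1e-12) {
        resi_error("Dirichlet weights must sum to 1 before scaling",
                   "resi_input_error")
      }
      ds <- structure(list(outcome = data$outcome, design = data$design,
                           case_weights = n * g),
                      class = "resi_dataset")
      fit <- catch(.refit(model, ds))
    }
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    s <- tryCatch(.s_hat_blocks(fit, blocks, flavor, oracle_cov),
                  resi_singular_covariance = function(e) NULL,
                  resi_degenerate_leverage = function(e) NULL)
    if (is.null(s)) {
      n_failed <- n_failed + 1L
      next
    }
    reps[r, ] <- s
  }
  if (all(is.na(reps))) {
    resi_error("every resample produced a degenerate fit or singular covariance",
               "resi_degenerate_data")
  }
  if (type == "nonparam" && n_failed > 0.1 * R) {
    resi_error(paste0(n_failed, "/", R, " resamples were rank deficient; ",
                      "consider the Bayesian bootstrap, which keeps every ",
                      "observation in each weighted refit"),
               "resi_degenerate_data")
  }
  list(replicates = reps, n_failed = n_failed)
}

.new_boot_result <- function(eng, blocks, alpha, method, seed, s_hat) {
  reps <- drop(eng$replicates)
  structure(list(replicates = reps,
                 interval = .percentile_interval(eng$replicates[, 1L], alpha),
                 s_hat = s_hat,
                 level = 1 - alpha,
                 method = method,
                 n_failed = eng$n_failed,
                 seed = seed),
            class = "resi_boot_result")
}

.spec_blocks <- function(data, model_spec) {
  model <- if (is.null(model_spec$model)) "linear" else model_spec$model
  bi <- model_spec$beta_index
  if (is.null(bi)) bi <- seq_len(ncol(data$design))[-1L]
  list(model = model, blocks = list(bi), oracle_cov = model_spec$oracle_cov)
}

#' Nonparametric percentile bootstrap CI for the RESI
#'
#' Draws \code{R} resamples of the n rows with replacement, refits the model
#' and recomputes the RESI estimate on each, and takes the empirical
#' \eqn{\alpha/2} and \eqn{1-\alpha/2} percentiles as the interval.
#' Rank-deficient resamples are redrawn up to 10 times and then skipped; if
#' more than 10\% of replicates fail this way an error recommends the
#' Bayesian bootstrap instead.
#'
#' @param data A \code{\link{resi_dataset}}.
#' @param model_spec List with \code{model} (\code{"linear"} or
#'   \code{"logistic"}), \code{beta_index} (columns of the target block;
#'   default: all non-intercept columns) and, for \code{flavor = "oracle"},
#'   \code{oracle_cov}: the known covariance of \code{sqrt(n)} times the
#'   target block estimate.
#' @param flavor Covariance flavor for the recomputed estimate
#'   (\code{"robust"}, \code{"parametric"}, or \code{"oracle"} with a
#'   supplied true covariance).
#' @param R Number of bootstrap replicates (default 1000).
#' @param alpha One minus the interval level.
#' @param seed Master seed; per-replicate substreams are derived from it so
#'   the result is reproducible and order-independent.
#'
#' @return A \code{resi_boot_result}: list with \code{replicates},
#'   \code{interval}, \code{s_hat} (full-data estimate), \code{level},
#'   \code{method}, \code{n_failed}, \code{seed}.
#' @export
nonparam_boot_ci <- function(data, model_spec = list(), flavor = "robust",
                             R = 1000L, alpha = 0.05, seed = NULL) {
  ms <- .spec_blocks(data, model_spec)
  full <- .refit(ms$model, data)
  s_hat <- .s_hat_blocks(full, ms$blocks, flavor, ms$oracle_cov)
  eng <- .resi_boot(data, ms$model, flavor, ms$blocks, R, alpha, seed,
                    type = "nonparam", oracle_cov = ms$oracle_cov)
  .new_boot_result(eng, ms$blocks, alpha, "boot", seed, s_hat)
}

#' Bayesian-bootstrap credible interval for the RESI
#'
#' For each replicate draws observation weights \eqn{g \sim
#' Dirichlet(1,\dots,1)}, refits by weighted regression with case weights
#' \eqn{n g} (so the Wald statistic's n-scaling is unchanged) and recomputes
#' the RESI. The replicates simulate the posterior of the effect size under
#' a flat improper prior, and the percentile interval is a credible
#' interval. Because every observation stays in every refit with an almost
#' surely positive weight, this interval remains usable where the
#' nonparametric bootstrap fails by resampling rank-deficient designs.
#'
#' @inheritParams nonparam_boot_ci
#' @param weight_sampler Testing hook: a \code{function(n)} returning a
#'   weight vector summing to 1; defaults to Dirichlet(1,...,1) draws.
#' @return A \code{resi_boot_result} with \code{method = "bayes_boot"}.
#' @export
bayes_boot_interval <- function(data, model_spec = list(), flavor = "robust",
                                R = 1000L, alpha = 0.05, seed = NULL,
                                weight_sampler = NULL) {
  ms <- .spec_blocks(data, model_spec)
  full <- .refit(ms$model, data)
  s_hat <- .s_hat_blocks(full, ms$blocks, flavor, ms$oracle_cov)
  eng <- .resi_boot(data, ms$model, flavor, ms$blocks, R, alpha, seed,
                    type = "bayes", oracle_cov = ms$oracle_cov,
                    weight_sampler = weight_sampler)
  .new_boot_result(eng, ms$blocks, alpha, "bayes_boot", seed, s_hat)
}

#' @export
print.resi_boot_result <- function(x, ...) {
  cat(sprintf("<resi_boot_result> %s: S_hat = %.4g, %.0f%% interval [%.4g, %.4g] (R = %d, failed = %d)\n",
              x$method, x$s_hat[1L], 100 * x$level, x$interval[1L],
              x$interval[2L],
              NROW(x$replicates), x$n_failed))
  invisible(x)
}
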