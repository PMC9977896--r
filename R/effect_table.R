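# ANOVA-style effect size reporting: one row per model term (multi-level
# factors tested as a block), an Overall row for all non-intercept
# coefficients jointly, and residual degrees of freedom. p-values always
# come from the central chi-squared distribution with the block's degrees
# of freedom, whatever the covariance flavor.

#' Effect size table for a fitted model
#'
#' Builds the reporting table: for each non-intercept term, that term's
#' coefficients form the target block (everything else is nuisance) and the
#' row carries the estimate (single-d.f. terms only), its standard error
#' under the chosen covariance flavor, the Wald chi-squared statistic, its
#' degrees of freedom, the central chi-squared p-value, the RESI point
#' estimate and an interval. A final \code{Overall} row tests all
#' non-intercept coefficients jointly.
#'
#' @param model A \code{resi_fit} (from \code{\link{fit_ols}},
#'   \code{\link{fit_ols_weighted}}, \code{\link{fit_logistic}} or the
#'   \code{\link{resi}} front end).
#' @param flavor Covariance flavor: \code{"robust"} (HC3 for linear fits,
#'   score sandwich for logistic) or \code{"parametric"}.
#' @param interval_method \code{"boot"}, \code{"bayes_boot"}, \code{"chisq"}
#'   or \code{"f"}.
#' @param level Interval level (default 0.95).
#' @param R Bootstrap replicates for the resampling methods.
#' @param seed Seed for the resampling methods.
#'
#' @return A data frame of class \code{resi_effect_table} with columns
#'   \code{factor}, \code{estimate}, \code{se}, \code{chisq}, \code{df},
#'   \code{p}, \code{resi}, \code{ci_lower}, \code{ci_upper}; attributes
#'   \code{residual_df} (n - m), \code{flavor}, \code{interval_method},
#'   \code{level}, \code{n}, \code{seed}.
#' @export
effect_table <- function(model, flavor = "robust", interval_method = "boot",
                         level = 0.95, R = 1000L, seed = NULL) {
  stopifnot(inherits(model, "resi_fit"), level > 0, level < 1)
  interval_method <- match.arg(interval_method,
                               c("boot", "bayes_boot", "chisq", "f"))
  alpha <- 1 - level
  data <- model$data
  assign <- attr(data, "term_assign")
  labels <- attr(data, "term_labels")
  if (is.null(assign)) {
    cn <- colnames(data$design)
    is_int <- seq_along(cn) == 1L & apply(data$design == 1, 2, all)
    assign <- cumsum(!is_int)
    assign[is_int] <- 0L
    labels <- cn[!is_int]
  }
  term_ids <- sort(unique(assign[assign > 0L]))
  blocks <- lapply(term_ids, function(k) which(assign == k))
  names(blocks) <- labels[term_ids]
  nonint <- which(assign > 0L)
  blocks <- c(blocks, list(Overall = nonint))

  V <- coef_covariance(model, flavor)
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    w <- wald_statistic(model$theta_hat[b], V[b, b, drop = FALSE],
                        n = model$n, flavor = flavor, m = model$m)
    data.frame(factor = names(blocks)[i],
               estimate = if (length(b) == 1L) model$theta_hat[b] else NA_real_,
               se = if (length(b) == 1L) sqrt(V[b, b]) else NA_real_,
               chisq = w$t2,
               df = w$m1,
               p = stats::pchisq(w$t2, df = w$m1, lower.tail = FALSE),
               resi = resi_point(w),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  if (interval_method %in% c("chisq", "f")) {
    ci <- t(vapply(seq_len(nrow(tab)), function(i) {
      iv <- if (interval_method == "chisq") {
        chisq_ncp_ci(tab$chisq[i], tab$df[i], alpha)
      } else {
        f_ncp_ci(tab$chisq[i], tab$df[i], model$n - model$m, alpha)
      }
      ncp_interval_to_resi(iv, model$n)
    }, numeric(2)))
  } else {
    mdl <- if (model$family == "binomial") "logistic" else "linear"
    eng <- .resi_boot(data, mdl, flavor, blocks, R = R, alpha = alpha,
                      seed = seed,
                      type = if (interval_method == "boot") "nonparam"
                             else "bayes")
    ci <- t(apply(eng$replicates, 2, .percentile_interval, alpha = alpha))
    attr(tab, "n_failed") <- eng$n_failed
  }
  tab$ci_lower <- ci[, 1L]
  tab$ci_upper <- ci[, 2L]

  attr(tab, "residual_df") <- model$n - model$m
  attr(tab, "flavor") <- flavor
  attr(tab, "interval_method") <- interval_method
  attr(tab, "level") <- level
  attr(tab, "n") <- model$n
  attr(tab, "seed") <- seed
  class(tab) <- c("resi_effect_table", "data.frame")
  tab
}

#' Fit a model and report RESI effect sizes
#'
#' One-call front end: builds the design matrix from a formula (character
#' and factor predictors are treatment-coded with the lexicographically
#' first level as reference), fits a linear or logistic model, and returns
#' the effect size table.
#'
#' @param formula Model formula, e.g. \code{accuracy ~ group + age + gender}.
#' @param data A data frame.
#' @param model \code{"linear"} or \code{"logistic"} (0/1 outcome).
#' @inheritParams effect_table
#' @return A \code{resi_effect_table}; see \code{\link{effect_table}}.
#' @export
resi <- function(formula, data, model = c("linear", "logistic"),
                 flavor = "robust", interval_method = "boot", level = 0.95,
                 R = 1000L, seed = NULL) {
  model <- match.arg(model)
  outcome <- deparse(formula[[2L]])
  preds <- attr(stats::terms(formula, data = data), "term.labels")
  ds <- build_dataset(data, outcome, preds)
  fit <- if (model == "logistic") fit_logistic(ds) else fit_ols(ds)
  effect_table(fit, flavor = flavor, interval_method = interval_method,
               level = level, R = R, seed = seed)
}

.fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3g", p))

#' @export
print.resi_effect_table <- function(x, digits = 2, ...) {
  lvl <- attr(x, "level")
  out <- data.frame(
    Factor = x$factor,
    Estimate = ifelse(is.na(x$estimate), "", sprintf("%.*f", digits, x$estimate)),
    `s.e.` = ifelse(is.na(x$se), "", sprintf("%.*f", digits, x$se)),
    `Chi-squared` = sprintf("%.*f", digits, x$chisq),
    d.f. = x$df,
    `p-value` = .fmt_p(x$p),
    RESI = sprintf("%.*f", digits, x$resi),
    CI = sprintf("(%.*f, %.*f)", digits, x$ci_lower, digits, x$ci_upper),
    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[8] <- sprintf("%.0f%% CI", 100 * lvl)
  out <- rbind(out, c("Residual", "", "", "", attr(x, "residual_df"),
                      "", "", ""))
  print(out, row.names = FALSE, right = FALSE)
  cat(sprintf("flavor: %s; interval: %s\n", attr(x, "flavor"),
              attr(x, "interval_method")))
  invisible(x)
}

#' Write an effect table to CSV
#'
#' Writes the table rows plus a trailing \code{Residual} row carrying the
#' residual degrees of freedom. A leading comment line records the package
#' version, flavor, interval method and seed so reruns are auditable.
#'
#' @param x A \code{resi_effect_table}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_effect_table <- function(x, path) {
  stopifnot(inherits(x, "resi_effect_table"))
  df <- as.data.frame(x)
  df <- rbind(df, data.frame(factor = "Residual", estimate = NA, se = NA,
                             chisq = NA, df = attr(x, "residual_df"), p = NA,
                             resi = NA, ci_lower = NA, ci_upper = NA))
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(x, "seed")
  writeLines(sprintf("# resindex %s; flavor=%s; interval=%s; level=%s; seed=%s",
                     as.character(utils::packageVersion("resindex")),
                     attr(x, "flavor"), attr(x, "interval_method"),
                     attr(x, "level"),
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
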