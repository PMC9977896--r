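---
title: "Methods: the robust effect size index and its intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the robust effect size index and its intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resindex)
```

## The estimand and its estimator

The robust effect size index (RESI) standardizes the deviation of a block of
target parameters $\beta \in \mathbb{R}^{m_1}$ from a reference value
$\beta_0$ (almost always zero) by the asymptotic covariance of the estimator:

$$S_\beta = \sqrt{(\beta - \beta_0)^\top \Sigma_\beta^{-1} (\beta - \beta_0)},$$

where $\Sigma_\beta$ is the covariance of $\sqrt{n}(\hat\beta - \beta)$.
Because $S_\beta$ is defined through the Wald statistic of an M-estimator it
carries no units, does not grow with $n$, and is comparable across model
families — the same quantity can be reported for a linear and a logistic
model of the same scientific effect.

The Wald statistic
$T^2 = n(\hat\beta - \beta_0)^\top \hat\Sigma_\beta^{-1}(\hat\beta - \beta_0)$
is approximately non-central $\chi^2_{m_1}$ with noncentrality
$\lambda = n S_\beta^2$. Equating the observed statistic to the mean of that
distribution ($m_1 + \lambda$) and solving for $S_\beta$ gives the truncated
point estimator implemented by `resi_point()`:

$$\hat S_\beta = \sqrt{\max\!\left(0, \frac{T^2 - m_1}{n}\right)}.$$

The truncation reflects that the estimand is nonnegative; it also means the
estimator piles mass at exactly 0 for null effects, which the bootstrap
intervals inherit (their lower bound is usually exactly 0 at small effects).

Three covariance flavors give three versions of $T^2$ and $\hat S$:

* **oracle** — the true $\Sigma_\beta$ is supplied (a simulation benchmark,
  not computable in applications);
* **parametric** — the model-based covariance, $\hat\sigma^2 (X^\top X)^{-1}$
  for least squares and the inverse expected information for logistic
  regression;
* **robust** — the heteroskedasticity-consistent sandwich. For least squares
  this is the HC3 (jackknife-type) form with meat
  $\sum_i e_i^2 (1-h_i)^{-2} x_i x_i^\top$, where $h_i$ is the leverage; for
  logistic models, where HC3 is not defined, it is the score sandwich
  $J^{-1} K J^{-1}/n$ built from per-observation scores. The choice of the
  score sandwich for logistic models is ours; the HC3 form is only defined
  for least squares, and the general M-estimation sandwich is the natural
  extension.

One scale convention is used everywhere: stored covariance matrices are for
$\hat\theta$ itself (already divided by $n$), so `wald_statistic()` applies
no extra factor of $n$. Covariance inputs are symmetrized as
$(A + A^\top)/2$ before inversion; a singular covariance fails with a typed
error rather than silently pseudo-inverting (a Moore–Penrose fallback exists
behind an explicit `allow_pseudoinverse` flag, for callers that know their
block is deliberately degenerate).

## Interval construction

### Inverting non-central distributions

Since $S^2 = \lambda / n$, a confidence interval for the noncentrality
parameter maps directly to one for the RESI. The CDF of the non-central
$\chi^2$ (or F) distribution at a fixed quantile is strictly decreasing in
$\lambda$, so each bound solves a monotone scalar equation:
$F(T^2_{obs}; m_1, \ell) = 1 - \alpha/2$ for the lower bound and
$F(T^2_{obs}; m_1, u) = \alpha/2$ for the upper. `chisq_ncp_ci()` and
`f_ncp_ci()` solve these by geometric bracket growth followed by bisection,
to $|F - \text{target}| < 10^{-8}$ in CDF space (bisection is guaranteed
here; no derivative information is needed). The bracket cap is
$\lambda_{max} = T^2 + 100\sqrt{T^2} + 1000$, far beyond any root the CDF
geometry allows. When no root exists in $[0, \infty)$ the bound is truncated
at 0 and flagged — never returned as missing. For the F family the observed
statistic is divided by $m_1$ first, matching
$T^2_{(p)}/m_1 \sim F(m_1, n-m; nS^2)$; the denominator degrees of freedom
are $n - m$.

These intervals are exact only for the oracle statistic with a fixed design.
When the covariance is estimated, the statistic's variance exceeds the
non-central $\chi^2$'s: by the F-moment expansion, the parametric statistic's
variance is larger than the oracle's by $2(2 m_1 S^2 + n S^4)$, and the
robust statistic's is larger still. The inflation *ratio* tends to
$1 + S^2/2$ for the parametric statistic — essentially constant in $n$ at
fixed $S$ — so in our experiments the $\chi^2$ CI's undercoverage for the
estimated-covariance statistics is severe (about 0.83–0.87 at $S = 1$) and
grows with the effect size, while being roughly flat across
$n \in [50, 1000]$. The acceptance suite asserts exactly this pattern:
undercoverage below nominal at $S = 1$ for both small and large $n$, and
monotone worsening from $S = 0.33$ to $S = 1$. We deliberately do not assert
a decrease between $n = 50$ and $n = 500$: the variance-ratio algebra above
implies no such trend at fixed $S$, and at 500 simulations such a comparison
would be decided by Monte Carlo noise.

### Bootstrap intervals

`nonparam_boot_ci()` draws $R$ resamples of full rows (outcome and
covariates together — a cases bootstrap, valid when the design is random),
refits, recomputes $\hat S$, and reports the empirical $\alpha/2$ and
$1-\alpha/2$ percentiles, taken as order statistics at
$\lceil R\alpha/2 \rceil$ and $\lceil R(1-\alpha/2) \rceil$ with ties kept.
Only the percentile method is provided; $R = 1000$ by default. Resamples
whose design is rank deficient (or whose sandwich is degenerate through a
unit leverage) are redrawn up to 10 times, then skipped and counted; if more
than 10% of replicates fail this way the function aborts with an error
recommending the Bayesian bootstrap.

`bayes_boot_interval()` draws observation weights
$g \sim \text{Dirichlet}(1, \dots, 1)$ per replicate, refits by weighted
regression with case weights $n g$ (rescaling keeps the Wald statistic's
$n$-scaling unchanged), and takes the same percentile rule. The replicates
simulate the posterior of $S$ under a flat improper prior, so the interval
has a credible-interval interpretation, and because every observation keeps
an almost surely positive weight the method remains usable for data that
break the nonparametric bootstrap (for instance a binary predictor with very
few observations in one category).

A consequential design choice sits in the weighted refit: case weights are
treated as *frequency* weights in the sandwich, i.e. the meat is
$\sum_i w_i e_i^2 x_i x_i^\top$, linear in $w_i$, not quadratic. A
multinomially resampled row of multiplicity $c_i$ contributes $c_i$ score
outer products, linearly — so the linear convention makes the weighted
sandwich the plug-in of the sandwich functional at the weighted empirical
distribution, which is the functional the Bayesian bootstrap is supposed to
sample. With the quadratic (score-of-weighted-objective) convention the
Dirichlet weight variability is double-counted: $E[w_i^2] \approx 2$, the
robust covariance roughly doubles, and every replicate's $\hat S$ is biased
downward — we observed credible intervals shifted well below the full-data
estimate before settling on the linear convention. With unit weights both
conventions coincide with the ordinary estimators.

Reproducibility: each interval takes one master seed; per-replicate
substreams are derived from it by a counter, so results do not depend on
evaluation order.

## Model fitting layer

Linear fits solve the (weighted) normal equations through a Cholesky
factorization of $X^\top W X$, with a relative tolerance on the Cholesky
diagonal serving as the rank check; rank deficiency raises a typed error the
bootstrap layer can catch. Leverages come from the closed form
$h_i = w_i x_i (X^\top W X)^{-1} x_i^\top$. Logistic fits use iteratively
reweighted least squares (`stats::glm.fit`) run to a deviance tolerance of
$10^{-12}$ with at most 50 iterations; a fit is declared separated when it
fails to converge or any coefficient exceeds 30 in absolute value, and the
error message carries the iteration count and score norm. $J$ and $K$ are
accumulated from the standard M-estimation definitions (average Hessian and
average score outer product) and validated in tests against the `sandwich` package
as an independent oracle.

`resi()` is the user-facing front end: it expands factors to treatment
coding (reference level = lexicographically first), fits, and reports an
ANOVA-style table with one row per term — multi-level factors tested as a
block with levels $-$ 1 degrees of freedom — plus an Overall row for all
non-intercept coefficients jointly and the residual degrees of freedom.
p-values always come from the central $\chi^2_{m_1}$ distribution,
regardless of the covariance flavor; the intercept is always treated as a
nuisance parameter.

## The simulation harness

`sim_scenario()` / `generate_dataset()` implement a simple linear model
$y = \beta_1 x + \epsilon$ with a binary covariate, crossing:

* error family: normal, or shifted Gamma — $\text{Gamma}(\alpha = 0.1)$
  draws recentered to mean zero, with moment skewness
  $2/\sqrt{0.1} \approx 6.32$;
* variance structure: homoskedastic ($\sigma^2 = 1$) or heteroskedastic
  ($\sigma_0^2 = 0.25$ when $x = 0$, $\sigma_1^2 = 2.25$ when $x = 1$; for
  the Gamma family the rate $\sqrt{0.1}/(x + 0.5)$ produces the same group
  variances);
* covariate mode: fixed — exactly $\lceil 0.3 n \rceil$ ones — or random
  Bernoulli(0.3).

The generator is parameterized by the effect size, not the slope: the slope
is recovered as $\beta_1 = S \sqrt{\Sigma_\beta}$ with
$\Sigma_\beta = \sigma^2 / (\pi(1-\pi))$ under homoskedasticity and
$\sigma_1^2/\pi + \sigma_0^2/(1-\pi)$ under heteroskedasticity. Under random
covariates the same fixed-$\pi$ formula defines the estimand ("true $S$");
this is a convention, validated by Monte Carlo recovery: the robust
estimator averaged over 1000 replicates at $n = 10^4$ lands within 0.01 of
the nominal $S$ in all eight scenario families.

What the generator does *not* emulate: continuous or multivariate
covariates, nuisance-covariate correlation, outcome contamination, and
model misspecification beyond heteroskedasticity and skewness. Passing
coverage here shows the interval machinery is calibrated for the mechanisms
studied — not that it is robust to everything real data can do.

`run_study()` crosses scenarios with estimator flavors and interval methods
and tabulates mean bias and empirical coverage, with the binomial Monte
Carlo standard error $\sqrt{p(1-p)/n_{sims}}$ attached to every cell.
Failures are confined to their cell (marked incomplete) rather than aborting
a grid.

## Problem sizes and numerical choices

Defaults match the full study design (1000 simulations, 1000 bootstrap
replicates, 95% intervals). The packaged acceptance checks use 500
simulations with 500 bootstrap replicates for the two bootstrap-coverage
results and 1000 simulations for the chi-squared/oracle result, with
tolerances stated in binomial standard errors of those sizes; the moment and
goodness-of-fit checks use 5000 replicates at $n = 500$, $S = 1$. These
sizes were chosen so each check's Monte Carlo error is small relative to the
effect being asserted.

Other numerical choices, collected: covariance symmetrization before
inversion; Cholesky-based rank detection with a relative tolerance of
roughly $4 m \epsilon$ on the squared diagonal; NCP bisection tolerance
$10^{-8}$ in CDF space with truncation at $\lambda = 0$ flagged, never
missing; percentile ties kept; bootstrap failure budget 10% with 10 redraws;
logistic separation threshold $|\hat\theta|_\infty > 30$.

## Known limitations

* Only linear and logistic models are supported; longitudinal, survival and
  other GLM families are out of scope.
* The oracle flavor requires the user to supply the true covariance, so it
  is only meaningful inside simulations.
* The non-central $\chi^2$/F intervals are provided for completeness and for
  the oracle/parametric cases where they are exact; for
  estimated-covariance statistics they undercover by construction, and the
  bootstrap intervals should be preferred — that asymmetry is the package's
  central message, not a defect to be fixed.
* Wild-bootstrap variants are not implemented.
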