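# resindex

Estimation and interval construction for the **robust effect size index
(RESI)** — a standardized, sample-size-free effect size for regression
models, defined from the Wald statistic of an M-estimator:

$$S_\beta = \sqrt{(\beta - \beta_0)^\top \Sigma_\beta^{-1} (\beta - \beta_0)},
\qquad
\hat S_\beta = \sqrt{\max\!\left(0, \frac{T^2 - m_1}{n}\right)},$$

where $\Sigma_\beta$ is the asymptotic covariance of
$\sqrt{n}(\hat\beta - \beta)$, $T^2$ the Wald chi-squared statistic for the
$m_1$ target coefficients, and $\beta_0$ a reference value (usually zero).
Because the definition runs through the Wald statistic, the same index can
be reported for linear and logistic models and compared across studies with
different sample sizes — useful for effect-size reporting in psychiatry,
epidemiology and psychology, where outcomes of the same construct are
sometimes analyzed as continuous and sometimes as binary.

The package provides:

* three flavors of the Wald statistic and RESI estimate — **oracle** (true
  covariance, a simulation benchmark), **parametric** (model-based
  covariance) and **robust** (HC3 sandwich for least squares, score sandwich
  for logistic regression);
* confidence intervals by **inversion of non-central chi-squared and F
  distributions** for the noncentrality parameter $\lambda = nS^2$
  (`chisq_ncp_ci()`, `f_ncp_ci()`), with truncation at zero instead of
  missing values;
* a **nonparametric percentile bootstrap CI** (`nonparam_boot_ci()`) and a
  **Bayesian-bootstrap credible interval** with Dirichlet(1, …, 1) weights
  (`bayes_boot_interval()`) — the recommended intervals, since the
  non-central-distribution CIs undercover whenever the covariance must be
  estimated;
* ANOVA-style **effect tables** (`resi()`, `effect_table()`) with one row
  per factor, an Overall row and residual degrees of freedom;
* a **simulation harness** (`sim_scenario()`, `generate_dataset()`,
  `run_study()`) for bias and interval-coverage studies under normal or
  heavily skewed (shifted-Gamma) errors, homo- or heteroskedastic variances,
  and fixed or random binary covariates;
* a thin command-line front end (`inst/cli/resindex`) with `fit` and
  `simulate` subcommands.

## Worked example

```r
library(resindex)
set.seed(2025)
n <- 130
group <- rep(c("control", "patient"), length.out = n)
age <- round(runif(n, 18, 60))
accuracy <- 0.78 - 0.10 * (group == "patient") - 0.002 * (age - 40) +
  rnorm(n, 0, 0.12)
dat <- data.frame(accuracy, group, age)

tab <- resi(accuracy ~ group + age, dat, model = "linear",
            flavor = "robust", interval_method = "boot", R = 1000, seed = 1)
print(tab)
```

```
 Factor   Estimate s.e. Chi-squared d.f. p-value RESI 95% CI
 group    -0.12    0.02 32.03       1    <0.001  0.49 (0.31, 0.69)
 age      -0.00    0.00 2.00        1    0.157   0.09 (0.00, 0.27)
 Overall                33.24       2    <0.001  0.49 (0.32, 0.70)
 Residual                           127
flavor: robust; interval: boot
```

Reading the table: the patient group scores 0.12 lower in accuracy than
controls after adjusting for age; the RESI of 0.49 is a moderate-to-large
standardized effect, with a 95% bootstrap CI of (0.31, 0.69) that does not
depend on the sample size the way the chi-squared statistic and p-value do.
The age effect is compatible with zero (RESI 0.09, CI touching 0 — the
estimator truncates at zero, so null effects pile up there). The Overall row
tests both non-intercept coefficients jointly (2 d.f.), and the Residual row
reports n − m = 127.

The same call with `model = "logistic"` on a binarized outcome reports the
index on the identical scale, which is the point of the RESI.

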