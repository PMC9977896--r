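Package: resindex
Title: Robust Effect Size Index Estimation with Confidence and Credible Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of the robust effect size index (RESI), a standardized
    effect size defined from Wald statistics that is comparable across linear
    and logistic models. Provides oracle, parametric and
    heteroskedasticity-consistent (sandwich) variants of the Wald statistic
    and the RESI point estimator; confidence intervals by inversion of
    non-central chi-squared and F distributions; nonparametric percentile
    bootstrap confidence intervals and Bayesian-bootstrap credible intervals;
    ANOVA-style effect size tables; and a simulation harness for bias and
    interval-coverage studies under homoskedastic or heteroskedastic, normal
    or skewed (shifted-Gamma) errors with fixed or random binary covariates.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
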