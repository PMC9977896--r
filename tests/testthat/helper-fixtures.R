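# Fixtures shared across test files; everything generated in code.

# Random regression dataset with intercept + (m - 1) continuous covariates.
make_lm_dataset <- function(n = 20, m = 3, sigma = 1, seed = 1) {
  set.seed(seed)
  X <- cbind(`(Intercept)` = 1,
             matrix(rnorm(n * (m - 1)), n,
                    dimnames = list(NULL, paste0("x", seq_len(m - 1)))))
  theta <- seq_len(m) / m
  resi_dataset(drop(X %*% theta) + rnorm(n, 0, sigma), X)
}

# Binary-covariate dataset matching the simulation design, fixed proportion.
make_binary_dataset <- function(n, b1, sd0 = 1, sd1 = sd0, pi = 0.3,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- ceiling(n * pi)
  x <- c(rep(1, n1), rep(0, n - n1))
  e <- rnorm(n, 0, ifelse(x == 1, sd1, sd0))
  resi_dataset(b1 * x + e, cbind(`(Intercept)` = 1, x = x))
}

# Small subject-level data frame for the formula / table / CLI layers.
make_study_df <- function(n = 98, seed = 10) {
  set.seed(seed)
  data.frame(
    accuracy = rnorm(n, 0.7, 0.1),
    group = rep(c("control", "patient"), length.out = n),
    age = round(runif(n, 18, 60)),
    gender = rep(c("female", "male"), each = ceiling(n / 2))[seq_len(n)])
}
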