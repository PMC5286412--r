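# Shared fixtures for the suite. All stochastic checks run under this
# fixed seed so they are reproducible.
STUDY_SEED <- 1L

# A flat reflectance spectrum on the analysis grid.
flat_spectrum <- function(value = 1) {
  reflectance_spectrum(analysis_grid(), rep(value, length(analysis_grid())))
}

# A raw spectrum with constant counts on the analysis grid.
const_raw <- function(counts, role = "sample") {
  raw_spectrum(analysis_grid(), rep(counts, length(analysis_grid())), role = role)
}

# Closed-form least-squares slope oracle (sigma formulas), independent of
# the lm-based implementation.
ols_slope_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# Brute-force one-way ANOVA oracle from explicit sums of squares.
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}
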