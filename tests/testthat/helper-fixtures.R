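# Shared fixtures for the suite.

study_deck <- function() deck_design(8, 8, 24)

both_designs <- function() {
  list(direct = direct_design(), indirect = study_deck())
}

# A small cohort configuration for structural tests (full-size cohorts are
# used only where a property genuinely needs them).
small_config <- function(n = 120, seed = 101, ...) {
  cohort_config(n = n, seed = seed, ...)
}

# Seeded covariates + response for regression tests: one numeric covariate,
# one two-level factor.
logit_fixture <- function(n = 200, seed = 42,
                          beta = c(-0.3, 0.8, 0.5)) {
  with_seed(seed, {
    df <- data.frame(x = rnorm(n),
                     g = factor(sample(c("a", "b"), n, TRUE)))
    mu <- plogis(beta[1] + beta[2] * df$x + beta[3] * (df$g == "b"))
    df$y <- rbinom(n, 1, mu)
    df
  })
}
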