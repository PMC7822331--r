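test_that("the likelihood reduces to Bernoulli-logit without a device", {
  df <- logit_fixture(n = 120, seed = 111)
  X <- model.matrix(~ x + g, df)
  beta <- c(0.2, -0.5, 0.9)
  ll <- rr_loglik(beta, X, df$y, 0, 1)
  mu <- plogis(drop(X %*% beta))
  expect_equal(ll$value, sum(dbinom(df$y, 1, mu, log = TRUE)))
  # one row, beta = 0, study device: lambda = 0.2 + 0.6 * 0.5 = 0.5
  ll1 <- rr_loglik(0, matrix(1), 1, 0.2, 0.6)
  expect_equal(ll1$value, log(0.5))
  expect_error(rr_loglik(beta, X, df$y, 0.5, 0.6), "c \\+ d <= 1")
})

test_that("the analytic gradient matches central finite differences", {
  df <- logit_fixture(n = 20, seed = 112)
  X <- model.matrix(~ x + g, df)
  beta <- c(0.3, -0.7, 0.4)
  for (cd in list(c(0, 1), c(0.2, 0.6))) {
    g <- rr_loglik(beta, X, df$y, cd[1], cd[2])$gradient
    fd <- vapply(seq_along(beta), function(j) {
      h <- 1e-6
      e <- replace(numeric(length(beta)), j, h)
      (rr_loglik(beta + e, X, df$y, cd[1], cd[2])$value -
         rr_loglik(beta - e, X, df$y, cd[1], cd[2])$value) / (2 * h)
    }, 0)
    expect_lt(max(abs(g - fd)), 1e-6)
  }
})

test_that("the device-free fit matches the IRLS logistic oracle", {
  df <- logit_fixture(n = 200, seed = 113)
  fit <- rr_glm(y ~ x + g, df, design = direct_design())
  oracle <- glm(y ~ x + g, binomial, df)
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit) - coef(oracle))), 1e-6)
  expect_lt(max(abs(fit$se - summary(oracle)$coefficients[, 2])), 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-10)
  expect_equal(AIC(fit), AIC(oracle), tolerance = 1e-8)
})

test_that("fit invariants hold: AIC identity, odds ratios, Wald pieces", {
  svy <- simulate_survey(small_config(n = 300, seed = 114))
  fit <- rr_glm(resp_theft ~ arm + oc_score, svy, both_designs())
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik, tolerance = 1e-9)
  expect_equal(fit$odds_ratio, exp(coef(fit)))
  expect_true(all(fit$se > 0))
  expect_equal(fit$wald_z, coef(fit) / fit$se)
  expect_equal(fit$wald_p, 2 * pnorm(-abs(fit$wald_z)))
  expect_lt(max(abs(rr_loglik(coef(fit), fit$X, fit$y, fit$cd[, "c"],
                              fit$cd[, "d"])$gradient)), 1e-8)
  # predictions: response = c + d * latent per arm
  mu <- predict(fit, type = "latent")
  lam <- predict(fit, type = "response")
  ind <- svy$arm == "indirect"
  expect_equal(lam[ind], 0.2 + 0.6 * mu[ind])
  expect_equal(lam[!ind], mu[!ind])
})

test_that("rank-deficient designs fail with the collinear column named", {
  df <- logit_fixture(n = 100, seed = 115)
  df$x2 <- 2 * df$x
  expect_error(rr_glm(y ~ x + x2, df, direct_design()), "x2")
})

test_that("reference-class recoding leaves fitted probabilities unchanged", {
  svy <- simulate_survey(small_config(n = 300, seed = 116))
  dz <- both_designs()
  f1 <- rr_glm(resp_theft ~ arm + education, svy, dz)
  svy2 <- svy
  svy2$education <- relevel(svy2$education, "higher")
  f2 <- rr_glm(resp_theft ~ arm + education, svy2, dz)
  expect_false(isTRUE(all.equal(coef(f1), coef(f2), check.attributes = FALSE)))
  expect_lt(max(abs(predict(f1, type = "response") -
                    predict(f2, type = "response"))), 1e-10)
})

test_that("coefficients are recovered from mixed-arm simulated data", {
  # moderate version of the recovery experiment (the acceptance suite runs
  # the full 200 replications)
  dz <- both_designs()
  truth <- c(0.6, 2.3, 0.06)
  ok <- vapply(seq_len(30), function(r) {
    df <- with_seed(11700 + r, {
      d <- data.frame(arm = factor(rep(c("direct", "indirect"), each = 1000),
                                   levels = c("direct", "indirect")),
                      x = pmin(pmax(rnorm(2000, 7, 5), 0), 40))
      mu <- plogis(truth[1] + truth[2] * (d$arm == "indirect") + truth[3] * d$x)
      lam <- ifelse(d$arm == "indirect", 0.2 + 0.6 * mu, mu)
      d$y <- rbinom(2000, 1, lam)
      d
    })
    fit <- rr_glm(y ~ arm + x, df, dz)
    all(abs(coef(fit) - truth) <= 2 * fit$se)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("Pearson statistic: oracle reduction, saturated fit, magnitude", {
  df <- logit_fixture(n = 200, seed = 118)
  fit <- rr_glm(y ~ x + g, df, direct_design())
  oracle <- glm(y ~ x + g, binomial, df)
  gof <- pearson_gof(fit)
  expect_equal(unname(gof$statistic),
               sum(residuals(oracle, "pearson")^2), tolerance = 1e-8)
  expect_equal(unname(gof$parameter), 200 - 3)
  # saturated fit: statistic collapses to ~0
  sep <- data.frame(y = rep(c(0, 1), each = 20), z = rep(c(0, 1), each = 20))
  fsep <- rr_glm(y ~ z, sep, direct_design())
  expect_lt(unname(suppressMessages(suppressWarnings(
    pearson_gof(fsep)))$statistic), 1e-3)
  # well-specified model: X^2 / df stays near 1 on average
  ratios <- vapply(seq_len(100), function(r) {
    d2 <- logit_fixture(n = 400, seed = 11900 + r)
    f2 <- rr_glm(y ~ x + g, d2, direct_design())
    unname(pearson_gof(f2)$statistic) / f2$df.residual
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("stepwise selection removes noise, keeps the method term, and is a fixed point", {
  dz <- both_designs()
  removed <- vapply(seq_len(200), function(r) {
    df <- with_seed(12000 + r, {
      d <- data.frame(arm = factor(rep(c("direct", "indirect"), each = 1000),
                                   levels = c("direct", "indirect")),
                      x = rnorm(2000), noise = rnorm(2000))
      mu <- plogis(0.2 + 1.5 * (d$arm == "indirect") + 0.8 * d$x)
      lam <- ifelse(d$arm == "indirect", 0.2 + 0.6 * mu, mu)
      d$y <- rbinom(2000, 1, lam)
      d
    })
    fit <- rr_glm(y ~ arm + x + noise, df, dz)
    sel <- step_rr_glm(fit)
    kept <- attr(terms(sel$formula), "term.labels")
    !("noise" %in% kept) && "arm" %in% kept && "x" %in% kept
  }, logical(1))
  expect_gte(mean(removed), 0.8)

  # a model already at a local AIC minimum is returned unchanged
  df <- with_seed(121, {
    d <- data.frame(arm = factor(rep(c("direct", "indirect"), each = 500),
                                 levels = c("direct", "indirect")),
                    x = rnorm(1000))
    mu <- plogis(0.2 + 1.5 * (d$arm == "indirect") + 0.8 * d$x)
    lam <- ifelse(d$arm == "indirect", 0.2 + 0.6 * mu, mu)
    d$y <- rbinom(1000, 1, lam)
    d
  })
  fit <- rr_glm(y ~ arm + x, df, dz)
  sel <- step_rr_glm(fit)
  expect_equal(coef(sel), coef(fit))
  expect_equal(nrow(attr(sel, "path")), 1)

  # the method term survives even when it carries no signal
  df$y2 <- with_seed(122, rbinom(1000, 1,
    ifelse(df$arm == "indirect", 0.2 + 0.6 * plogis(0.5), plogis(0.5))))
  fit2 <- rr_glm(y2 ~ arm + x, df, dz)
  sel2 <- step_rr_glm(fit2)
  expect_true("arm" %in% attr(terms(sel2$formula), "term.labels"))
})

test_that("categorical terms move as whole blocks in stepwise selection", {
  svy <- simulate_survey(small_config(n = 400, seed = 123))
  fit <- rr_glm(resp_theft ~ arm + education + oc_score, svy, both_designs())
  sel <- step_rr_glm(fit)
  kept <- attr(terms(sel$formula), "term.labels")
  # education either fully present or fully absent, never single dummies
  expect_true(all(kept %in% c("arm", "education", "oc_score")))
})

test_that("simulate() and residuals() are consistent with the fitted response law", {
  svy <- simulate_survey(small_config(n = 300, seed = 124))
  fit <- rr_glm(resp_theft ~ arm + oc_score, svy, both_designs())
  sims <- simulate(fit, nsim = 200, seed = 125)
  expect_equal(dim(sims), c(300, 200))
  emp <- rowMeans(sims)
  expect_lt(max(abs(emp - fit$fitted_lambda)), 4 * sqrt(0.25 / 200) + 1e-9)
  r <- residuals(fit, "pearson")
  p <- fit$fitted_lambda
  expect_equal(r, (fit$y - p) / sqrt(p * (1 - p)))
})
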