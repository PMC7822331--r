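test_that("the default cohort reproduces the configured categorical counts", {
  cfg <- cohort_config(seed = 11)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 792)
  expect_equal(as.vector(table(cohort$education)), c(125, 377, 207, 83))
  expect_equal(as.vector(table(cohort$conduct)), c(449, 301, 42))
  expect_equal(as.vector(table(cohort$nationality)), c(747, 45))
  # the published marital/crime columns sum to 790; the residual category
  # absorbs the two unclassified respondents
  expect_equal(as.vector(table(cohort$marital_status)), c(378, 160, 113, 141))
  expect_equal(as.vector(table(cohort$crime)), c(335, 119, 52, 49, 237))
})

test_that("numeric covariates respect their bounds and rough moments", {
  cohort <- generate_cohort(cohort_config(seed = 12))
  expect_true(all(cohort$age >= 18 & cohort$age <= 55))
  expect_true(all(cohort$sentence_months >= 0))
  expect_true(all(cohort$oc_score >= 0 & cohort$oc_score <= 40))
  expect_lt(abs(mean(cohort$age) - 37.01), 2)
  expect_lt(abs(mean(cohort$sentence_months) - 69.76), 12)
})

test_that("latent prevalences are calibrated to their targets", {
  cfg <- cohort_config(seed = 13)
  cohort <- generate_cohort(cfg)
  targets <- vapply(cfg$behaviour_model, `[[`, 0, "prevalence")
  for (b in names(targets)) {
    p <- mean(cohort[[paste0("true_", b)]])
    tol <- 4 * sqrt(targets[[b]] * (1 - targets[[b]]) / 792) + 1e-3
    expect_lt(abs(p - targets[[b]]), tol)
  }
})

test_that("generation is deterministic given the seed and empty cohorts work", {
  a <- generate_cohort(small_config(seed = 21))
  b <- generate_cohort(small_config(seed = 21))
  expect_identical(a, b)
  c2 <- generate_cohort(small_config(seed = 22))
  expect_false(identical(a$true_theft, c2$true_theft))
  empty <- generate_cohort(cohort_config(n = 0, seed = 1))
  expect_equal(nrow(empty), 0)
  expect_true(all(paste0("true_", c("theft", "arson")) %in% names(empty)))
})

test_that("configs reject malformed marginals and rates", {
  expect_error(cohort_config(covariate_marginals =
    list(education = c(nursery = 1))), "unknown education categor")
  expect_error(cohort_config(n = 100, covariate_marginals =
    list(education = c(none = 10, primary = 20, secondary = 30, higher = 30))),
    "sum to n")
  expect_error(cohort_config(arm_split = 1), "between 0 and 1")
  expect_error(cohort_config(dq_report_rate = c(theft = 1.2)),
               "named for every behaviour|\\[0, 1\\]")
  expect_error(cohort_config(n = -5), "non-negative")
})

test_that("arm assignment follows the rounding rule and attaches to positions", {
  cohort <- generate_cohort(small_config(n = 792, seed = 31))
  assigned <- assign_arms(cohort, 0.5, seed = 32)
  expect_equal(as.vector(table(assigned$arm)), c(396, 396))
  # n = 3: round-half-to-even gives 2 indirect, 1 direct
  tiny <- assign_arms(data.frame(id = 1:3), 0.5, seed = 1)
  expect_equal(sum(tiny$arm == "indirect"), 2)
  # the seed randomizes positions, so reversing the rows moves the labels
  fwd <- assign_arms(cohort, 0.5, seed = 33)
  rev_ <- assign_arms(cohort[rev(seq_len(nrow(cohort))), ], 0.5, seed = 33)
  expect_false(identical(fwd$arm[order(fwd$id)], rev_$arm[order(rev_$id)]))
})

test_that("response mechanism: identity case and arm-specific biases", {
  cfg <- small_config(n = 400, seed = 41, dq_report_rate = 1)
  cohort <- assign_arms(generate_cohort(cfg), 0.5, seed = 42)
  # no lying, no device: observed answers equal the latent truth
  ident <- apply_response_mechanism(cohort, direct_design(), 1, seed = 43)
  for (b in cfg$behaviours)
    expect_identical(ident[[paste0("resp_", b)]],
                     ident[[paste0("true_", b)]])
  expect_error(apply_response_mechanism(generate_cohort(cfg)),
               "arm")
})

test_that("observed rates converge to the mechanism's closed forms", {
  # large single-behaviour cohort: direct arm ~ pi * report_rate,
  # indirect arm ~ c + d * pi
  n <- 1e5
  truth <- with_seed(51, rbinom(n, 1, 0.8329))
  cohort <- data.frame(id = seq_len(n), true_theft = truth)
  cohort <- assign_arms(cohort, 0.5, seed = 52)
  out <- apply_response_mechanism(cohort, study_deck(),
                                  c(theft = 0.6918), seed = 53)
  direct_rate <- mean(out$resp_theft[out$arm == "direct"])
  indirect_rate <- mean(out$resp_theft[out$arm == "indirect"])
  expect_lt(abs(direct_rate - 0.8329 * 0.6918), 0.007)
  expect_lt(abs(indirect_rate - 0.69974), 0.007)
})

test_that("end-to-end: the indirect arm recovers the configured prevalence", {
  # generate -> assign -> randomize -> estimate, 200 replications; the
  # estimate should sit within 3 estimated SEs of the target almost always
  target <- 0.8329
  inside <- vapply(seq_len(200), function(r) {
    cfg <- cohort_config(n = 792, behaviours = "theft", seed = 6000 + r)
    svy <- simulate_survey(cfg)
    est <- estimate_prevalence(svy$resp_theft[svy$arm == "indirect"],
                               study_deck())
    abs(est$estimate_raw - target) <= 3 * est$se
  }, logical(1))
  expect_gte(mean(inside), 0.99)
})

test_that("the direct arm converges to prevalence times reporting rate", {
  # the social-desirability gap: with report rate < 1 the direct-arm
  # estimator is biased toward pi * rate, not pi
  n <- 4e4
  truth <- with_seed(61, rbinom(n, 1, 0.8329))
  cohort <- assign_arms(data.frame(id = 1:n, true_theft = truth), 0.5,
                        seed = 62)
  out <- apply_response_mechanism(cohort, study_deck(), c(theft = 0.6918),
                                  seed = 63)
  est <- estimate_prevalence(out$resp_theft[out$arm == "direct"],
                             direct_design())
  expect_lt(abs(est$estimate - 0.8329 * 0.6918), 0.012)
  expect_gt(abs(est$estimate - 0.8329), 0.1)
})
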