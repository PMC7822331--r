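test_that("the estimator inverts the misclassification line", {
  d <- study_deck()
  # all-no answers floor at 0 after truncation, raw estimate is -c/d
  est <- estimate_prevalence(rep(0L, 100), d)
  expect_equal(est$observed_rate, 0)
  expect_equal(est$estimate_raw, -1 / 3)
  expect_equal(est$estimate, 0)
  expect_equal(est$ci_low, 0)
  # direct questioning reduces to the sample proportion: 10-record fixture
  # with 6 yes answers
  y <- c(1, 1, 0, 1, 0, 1, 1, 0, 0, 1)
  est2 <- estimate_prevalence(y, direct_design())
  expect_equal(est2$estimate, 0.6)
  expect_equal(est2$variance, 0.6 * 0.4 / 9)
  # a worked inversion: observed rate 0.69974 under the study deck
  y3 <- c(rep(1L, 34987), rep(0L, 15013))
  est3 <- estimate_prevalence(y3, d)
  expect_equal(est3$estimate, (0.69974 - 0.2) / 0.6)
})

test_that("weighted estimation reduces to the weighted mean and guards input", {
  y <- c(1, 1, 0, 0)
  w <- c(3, 1, 1, 1)
  est <- estimate_prevalence(y, direct_design(), weights = w)
  expect_equal(est$observed_rate, 4 / 6)
  expect_error(estimate_prevalence(c(1), direct_design()), "at least 2")
  expect_error(estimate_prevalence(c(1, 2), direct_design()), "0/1")
  expect_error(estimate_prevalence(y, direct_design(), weights = c(1, -1, 1, 1)),
               "positive")
})

test_that("Wald intervals truncate to the unit interval", {
  # published indirect-arm summaries whose upper bounds print as 1.0000
  drugs <- prevalence_from_summary(0.9983, 0.0010)
  expect_equal(drugs$ci_high, 1)
  expect_equal(round(drugs$ci_low, 4), 0.9363)
  speeding <- prevalence_from_summary(0.9418, 0.0012)
  expect_equal(speeding$ci_high, 1)
  low <- prevalence_from_summary(0.01, 0.0010)
  expect_equal(low$ci_low, 0)
  inner <- prevalence_from_summary(0.5, 0.0004, level = 0.95)
  expect_equal(inner$ci_low, 0.5 - qnorm(0.975) * 0.02)
  expect_equal(inner$ci_high, 0.5 + qnorm(0.975) * 0.02)
  expect_true(inner$ci_low <= inner$estimate & inner$estimate <= inner$ci_high)
})

test_that("the estimator is unbiased across simulated surveys", {
  d <- study_deck()
  lam <- response_probability(d, 0.58)
  ests <- with_seed(71, vapply(seq_len(500), function(i) {
    estimate_prevalence(rbinom(396, 1, lam), d)$estimate_raw
  }, 0))
  expect_lt(abs(mean(ests) - 0.58), 0.012)
  # and its estimated variance tracks the closed form
  vs <- with_seed(72, vapply(seq_len(200), function(i) {
    estimate_prevalence(rbinom(396, 1, lam), d)$variance
  }, 0))
  expect_lt(abs(mean(vs) - prevalence_variance(d, 0.58, 396)), 2e-4)
})

test_that("subgroup estimates partition the cohort and match arm designs", {
  svy <- simulate_survey(small_config(n = 300, seed = 81))
  tab <- subgroup_estimates(svy, "theft", "education", both_designs())
  expect_equal(nrow(tab), 4 * 2)
  # subgroup counts partition each arm
  for (a in c("direct", "indirect"))
    expect_equal(sum(tab$n[tab$arm == a]), sum(svy$arm == a))
  # a single-category covariate reproduces the global estimate
  svy$onecat <- factor(rep("spanish", nrow(svy)),
                       levels = c("spanish", "other"))
  names(svy)[names(svy) == "nationality"] <- "nat_orig"
  names(svy)[names(svy) == "onecat"] <- "nationality"
  tab1 <- subgroup_estimates(svy, "theft", "nationality", both_designs())
  glob <- estimate_prevalence(svy$resp_theft[svy$arm == "indirect"],
                              study_deck())
  row <- tab1[tab1$category == "spanish" & tab1$arm == "indirect", ]
  expect_equal(row$estimate, glob$estimate)
  expect_equal(row$variance, glob$variance)
  # empty categories are flagged with absent variance
  empty_rows <- tab1[tab1$category == "other", ]
  expect_true(all(empty_rows$flagged))
  expect_true(all(is.na(empty_rows$variance)))
  expect_error(subgroup_estimates(svy, "theft", "shoe_size", both_designs()),
               "unknown covariate")
})

test_that("homogeneous subgroups scatter within 3 SE of the global estimate", {
  # homogeneous latent model (no covariate effects): every education
  # subgroup estimates the same prevalence
  bm <- list(theft = list(prevalence = 0.6, coef = list()))
  bad <- 0L; total <- 0L
  for (r in seq_len(100)) {
    cfg <- cohort_config(n = 792, behaviours = "theft", behaviour_model = bm,
                         dq_report_rate = c(theft = 1), seed = 8200 + r)
    svy <- simulate_survey(cfg)
    glob <- estimate_prevalence(svy$resp_theft[svy$arm == "indirect"],
                                study_deck())
    tab <- subgroup_estimates(svy, "theft", "education", both_designs())
    sub <- tab[tab$arm == "indirect" & !tab$flagged, ]
    dev <- abs(sub$estimate_raw - glob$estimate_raw) / sqrt(sub$variance)
    bad <- bad + sum(dev > 3)
    total <- total + nrow(sub)
  }
  expect_lt(bad / total, 0.01)
})
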