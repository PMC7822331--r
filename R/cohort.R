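# Canonical covariate vocabularies (reference class first: these are the
# reference levels used by the regression models).
covariate_levels <- function() {
  list(
    education      = c("none", "primary", "secondary", "higher"),
    marital_status = c("single", "married", "divorced", "cohabiting"),
    nationality    = c("spanish", "other"),
    crime          = c("theft", "violence", "sex_crime", "homicide_murder",
                       "other"),
    conduct        = c("model", "acceptable", "wrong")
  )
}

behaviour_names <- function() c("theft", "drugs", "violence", "speeding", "arson")

# Default categorical marginals of the emulated survey (792 male inmates).
# The published marital-status and crime columns sum to 790; the residual
# two respondents are assigned to the largest / residual category so the
# marginals total n (see the methods vignette).
default_covariate_marginals <- function() {
  list(
    education      = c(none = 125, primary = 377, secondary = 207, higher = 83),
    marital_status = c(single = 378, married = 160, divorced = 113,
                       cohabiting = 141),
    nationality    = c(spanish = 747, other = 45),
    crime          = c(theft = 335, violence = 119, sex_crime = 52,
                       homicide_murder = 49, other = 237),
    conduct        = c(model = 449, acceptable = 301, wrong = 42)
  )
}

# Latent-status logistic models per behaviour. Intercepts are calibrated at
# generation time so the cohort-average latent probability equals
# `prevalence` (the indirect-arm estimates of the emulated survey); slope
# coefficients default to the published regression point estimates where
# printed and 0 otherwise.
default_behaviour_model <- function() {
  list(
    theft = list(prevalence = 0.8329, coef = list(
      marital_status = c(married = -0.7398, divorced = -0.0104,
                         cohabiting = 0.3850),
      crime = c(violence = -1.7879, sex_crime = -3.0138,
                homicide_murder = -2.2686, other = -1.8188),
      conduct = c(acceptable = 0.4243, wrong = 1.9446),
      sentence_months = 0.0065, oc_score = 0.0585)),
    drugs = list(prevalence = 0.9983, coef = list(
      marital_status = c(married = -0.4495, divorced = -0.7704,
                         cohabiting = -0.5358),
      education = c(primary = -0.4209, secondary = -0.2257, higher = -1.5319),
      crime = c(violence = -0.7216, sex_crime = -1.5822,
                homicide_murder = -0.9157, other = -0.5373),
      conduct = c(acceptable = 0.7571, wrong = 1.6734),
      oc_score = 0.0724)),
    violence = list(prevalence = 0.5867, coef = list()),
    speeding = list(prevalence = 0.9418, coef = list()),
    arson = list(prevalence = 0.2679, coef = list(
      crime = c(violence = -0.8972, sex_crime = 0.9746,
                homicide_murder = -1.1933, other = 0.0095),
      oc_score = 0.0673))
  )
}

# Probability that a true positive admits the behaviour under direct
# questioning (true negatives never falsely confess). Calibrated as the
# ratio of the emulated survey's direct to indirect estimates.
default_dq_report_rate <- function() {
  c(theft = 0.6918, drugs = 0.7033, violence = 0.5117,
    speeding = 0.7661, arson = 0.2800)
}

#' Configuration of a synthetic survey cohort
#'
#' Bundles and validates everything the simulator needs: cohort size, arm
#' split, covariate marginals, moments of the numeric covariates, the
#' latent-status logistic model per behaviour, and the direct-questioning
#' reporting rates. The defaults emulate the motivating survey: 792 adult
#' male inmates of a Spanish prison, aged 18-55, questioned on five
#' sensitive behaviours (theft, illicit drug use, violence against property,
#' speeding, arson) with a 40-card deck device in the indirect arm.
#'
#' @param n Cohort size.
#' @param arm_split Proportion assigned to the indirect (randomized-response)
#'   arm; strictly between 0 and 1.
#' @param behaviours Behaviours to simulate (subset of the five defaults).
#' @param covariate_marginals Named list of category maps, one per covariate;
#'   each either integer counts summing to `n` or probabilities summing to 1
#'   (converted to counts by largest remainder). Default: the emulated
#'   survey's counts, rescaled to proportions when `n` differs from 792.
#' @param age_mean,age_sd,age_bounds Moments and truncation bounds (years) of
#'   the age distribution.
#' @param sentence_mean,sentence_sd Mean and SD (months) of the sentence
#'   length, matched by a log-normal.
#' @param oc_mean,oc_sd Moments of the 0-40 obsessive-compulsive severity
#'   score, matched by a truncated normal rounded to integers.
#' @param behaviour_model Per-behaviour list with `prevalence` (target
#'   population prevalence; intercept calibrated to it) and `coef` (named
#'   coefficient map on the covariates).
#' @param dq_report_rate Named per-behaviour probability that a true positive
#'   answers "yes" under direct questioning.
#' @param seed Integer master seed; `NULL` uses the caller's RNG stream.
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()], [simulate_survey()]
#' @export
cohort_config <- function(n = 792L,
                          arm_split = 0.5,
                          behaviours = behaviour_names(),
                          covariate_marginals = NULL,
                          age_mean = 37.01, age_sd = 9.317,
                          age_bounds = c(18, 55),
                          sentence_mean = 69.76, sentence_sd = 72.626,
                          oc_mean = 7.34, oc_sd = 7.121,
                          behaviour_model = default_behaviour_model(),
                          dq_report_rate = default_dq_report_rate(),
                          seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop_invalid("`n` must be a non-negative integer")
  n <- as.integer(n)
  if (!is.numeric(arm_split) || arm_split <= 0 || arm_split >= 1)
    stop_invalid("`arm_split` must lie strictly between 0 and 1")
  if (!all(behaviours %in% names(behaviour_model)))
    stop_invalid("every behaviour needs an entry in `behaviour_model`")
  behaviour_model <- behaviour_model[behaviours]
  if (is.null(covariate_marginals)) {
    covariate_marginals <- default_covariate_marginals()
    # defaults are counts for the emulated n = 792; rescale to proportions
    # for any other cohort size
    if (n != 792L)
      covariate_marginals <- lapply(covariate_marginals, function(m) m / sum(m))
  }
  vocab <- covariate_levels()
  if (!all(names(covariate_marginals) %in% names(vocab)))
    stop_invalid("unknown covariate(s) in marginals: ",
                 paste(setdiff(names(covariate_marginals), names(vocab)),
                       collapse = ", "))
  counts <- list()
  for (cv in names(covariate_marginals)) {
    m <- covariate_marginals[[cv]]
    bad <- setdiff(names(m), vocab[[cv]])
    if (length(bad))
      stop_invalid("unknown ", cv, " categor", if (length(bad) > 1) "ies: "
                   else "y: ", paste(bad, collapse = ", "))
    if (anyNA(m) || any(m < 0))
      stop_invalid("marginal for ", cv, " has negative or missing entries")
    if (abs(sum(m) - 1) <= 1e-9) {
      counts[[cv]] <- largest_remainder_counts(m, n)
    } else if (n > 0 && abs(sum(m) - n) <= 1e-9) {
      if (any(m != round(m)))
        stop_invalid("count marginal for ", cv, " has non-integer entries")
      counts[[cv]] <- m
    } else if (n == 0) {
      counts[[cv]] <- m * 0
    } else {
      stop_invalid("marginal for ", cv, " must sum to n = ", n,
                   " (counts) or to 1 (probabilities); got ", sum(m))
    }
  }
  rate <- dq_report_rate
  if (length(rate) == 1L && is.null(names(rate)))
    rate <- stats::setNames(rep(rate, length(behaviours)), behaviours)
  if (!all(behaviours %in% names(rate)))
    stop_invalid("`dq_report_rate` must be named for every behaviour")
  rate <- rate[behaviours]
  if (anyNA(rate) || any(rate < 0) || any(rate > 1))
    stop_invalid("`dq_report_rate` values must lie in [0, 1]")
  for (b in behaviours) {
    p <- behaviour_model[[b]]$prevalence
    if (is.null(p) || p < 0 || p > 1)
      stop_invalid("behaviour_model$", b, " needs a `prevalence` in [0, 1]")
  }
  if (age_bounds[1] >= age_bounds[2]) stop_invalid("invalid `age_bounds`")
  structure(
    list(n = n, arm_split = arm_split, behaviours = behaviours,
         covariate_counts = counts,
         age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
         sentence_mean = sentence_mean, sentence_sd = sentence_sd,
         oc_mean = oc_mean, oc_sd = oc_sd,
         behaviour_model = behaviour_model, dq_report_rate = rate,
         seed = seed),
    class = "cohort_config"
  )
}

# Convert a probability marginal into integer counts summing to n.
largest_remainder_counts <- function(p, n) {
  raw <- p / sum(p) * n
  base <- floor(raw)
  short <- round(n - sum(base))
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  base
}

# Inverse-CDF sampler for a normal truncated to [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Linear predictor of a behaviour's latent-status model, without intercept.
latent_offset <- function(model, cohort) {
  off <- rep(0, nrow(cohort))
  for (term in names(model$coef)) {
    cf <- model$coef[[term]]
    if (!term %in% names(cohort))
      stop_invalid("behaviour model refers to unknown covariate '", term, "'")
    if (is.null(names(cf))) {
      off <- off + cf * cohort[[term]]          # numeric covariate
    } else {
      v <- as.character(cohort[[term]])         # categorical: reference = 0
      hit <- cf[v]
      hit[is.na(hit)] <- 0
      off <- off + unname(hit)
    }
  }
  off
}

#' Generate a synthetic respondent cohort
#'
#' Draws a cohort matching the configured covariate structure exactly:
#' categorical covariates are sampled without replacement from the multiset
#' implied by the count marginals (so realized counts equal the configured
#' ones), age and the obsessive-compulsive score come from truncated normals
#' (rounded to whole years / points), sentence length from a moment-matched
#' log-normal (rounded to whole months), and each behaviour's latent true
#' status from its logistic model, whose intercept is calibrated by
#' root-finding so the cohort-average latent probability equals the target
#' prevalence. Deterministic given the config seed. Arms and observed
#' answers are added by [assign_arms()] and [apply_response_mechanism()].
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `id`, the five covariate factors, `age`,
#'   `sentence_months`, `oc_score`, and one `true_<behaviour>` 0/1 column
#'   per configured behaviour.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_invalid("`config` must be a cohort_config")
  n <- config$n
  with_seed(config$seed, {
    cohort <- data.frame(id = seq_len(n))
    vocab <- covariate_levels()
    for (cv in names(config$covariate_counts)) {
      cnt <- config$covariate_counts[[cv]]
      pool <- rep(names(cnt), times = cnt)
      cohort[[cv]] <- factor(if (n > 0) sample(pool) else character(0),
                             levels = vocab[[cv]])
    }
    cohort$age <- round(rtruncnorm(n, config$age_mean, config$age_sd,
                                   config$age_bounds[1], config$age_bounds[2]))
    meanlog <- log(config$sentence_mean) -
      0.5 * log(1 + (config$sentence_sd / config$sentence_mean)^2)
    sdlog <- sqrt(log(1 + (config$sentence_sd / config$sentence_mean)^2))
    cohort$sentence_months <- round(stats::rlnorm(n, meanlog, sdlog))
    cohort$oc_score <- round(rtruncnorm(n, config$oc_mean, config$oc_sd, 0, 40))
    for (b in config$behaviours) {
      model <- config$behaviour_model[[b]]
      target <- model$prevalence
      off <- latent_offset(model, cohort)
      if (n > 0) {
        intercept <- if (!is.null(model$intercept)) model$intercept
          else if (target <= 0) -Inf else if (target >= 1) Inf
          else stats::uniroot(function(a) mean(stats::plogis(a + off)) - target,
                              interval = c(-40, 40), tol = 1e-10)$root
        cohort[[paste0("true_", b)]] <-
          stats::rbinom(n, 1L, stats::plogis(intercept + off))
      } else {
        cohort[[paste0("true_", b)]] <- integer(0)
      }
    }
    cohort
  })
}

#' Randomly assign respondents to questioning arms
#'
#' A seeded uniform permutation assigns `round(n * arm_split)` respondents
#' (round-half-to-even, so a 0.5 split of n = 792 gives 396/396 and of
#' n = 3 gives 2 indirect, 1 direct) to the indirect arm; the rest answer
#' under direct questioning. Assignment attaches to positions, so permuting
#' respondent order under the same seed changes who lands in which arm.
#'
#' @param cohort Respondent data frame.
#' @param arm_split Proportion for the indirect arm, in (0, 1).
#' @param seed Optional integer seed.
#' @return The cohort with an `arm` factor (`direct`, `indirect`).
#' @export
assign_arms <- function(cohort, arm_split = 0.5, seed = NULL) {
  if (arm_split <= 0 || arm_split >= 1)
    stop_invalid("`arm_split` must lie strictly between 0 and 1")
  n <- nrow(cohort)
  n_ind <- round(n * arm_split)
  arm <- rep("direct", n)
  idx <- with_seed(seed, sample.int(n, n_ind))
  arm[idx] <- "indirect"
  cohort$arm <- factor(arm, levels = c("direct", "indirect"))
  cohort
}

#' Generate observed answers from latent statuses
#'
#' Indirect-arm respondents answer through the randomization device
#' ([randomize_response()]); direct-arm respondents exhibit one-sided
#' under-reporting: a true positive admits the behaviour with probability
#' `dq_report_rate[behaviour]`, a true negative always answers "no" (no
#' false confessions). This is the social-desirability mechanism whose
#' signature the comparison module measures.
#'
#' @param cohort Respondent data frame with `arm` and `true_<behaviour>`
#'   columns.
#' @param design [rr_design()] used in the indirect arm.
#' @param dq_report_rate Named per-behaviour reporting probabilities (or one
#'   number recycled).
#' @param seed Optional integer seed.
#' @return The cohort with one `resp_<behaviour>` 0/1 column per behaviour.
#' @export
apply_response_mechanism <- function(cohort, design = deck_design(8, 8, 24),
                                     dq_report_rate = default_dq_report_rate(),
                                     seed = NULL) {
  if (!"arm" %in% names(cohort))
    stop_invalid("cohort has no `arm` column; run assign_arms() first")
  behaviours <- sub("^true_", "", grep("^true_", names(cohort), value = TRUE))
  if (!length(behaviours))
    stop_invalid("cohort has no `true_*` columns; latent statuses are required")
  if (length(dq_report_rate) == 1L && is.null(names(dq_report_rate)))
    dq_report_rate <- stats::setNames(rep(dq_report_rate, length(behaviours)),
                                      behaviours)
  if (!all(behaviours %in% names(dq_report_rate)))
    stop_invalid("`dq_report_rate` must cover: ",
                 paste(behaviours, collapse = ", "))
  ind <- cohort$arm == "indirect"
  with_seed(seed, {
    for (b in behaviours) {
      truth <- cohort[[paste0("true_", b)]]
      if (anyNA(truth)) stop_invalid("missing true status for '", b, "'")
      y <- integer(nrow(cohort))
      if (any(ind)) y[ind] <- randomize_response(truth[ind], design)
      if (any(!ind)) {
        adm <- stats::rbinom(sum(!ind), 1L, dq_report_rate[[b]])
        y[!ind] <- as.integer(truth[!ind] == 1L & adm == 1L)
      }
      cohort[[paste0("resp_", b)]] <- y
    }
    cohort
  })
}

#' Simulate a complete survey
#'
#' Convenience wrapper running [generate_cohort()], [assign_arms()] and
#' [apply_response_mechanism()] with independent substreams derived from the
#' config's master seed, so the three stages are individually reproducible.
#'
#' @param config A [cohort_config()].
#' @param design [rr_design()] for the indirect arm.
#' @return Respondent data frame with covariates, latent statuses, `arm` and
#'   observed `resp_*` answers.
#' @examples
#' svy <- simulate_survey(cohort_config(n = 200, seed = 1))
#' table(svy$arm)
#' @export
simulate_survey <- function(config, design = deck_design(8, 8, 24)) {
  seeds <- derive_seeds(config$seed, 3)
  cfg <- config
  cfg$seed <- seeds[[1]]
  cohort <- generate_cohort(cfg)
  cohort <- assign_arms(cohort, config$arm_split, seed = seeds[[2]])
  apply_response_mechanism(cohort, design, config$dq_report_rate,
                           seed = seeds[[3]])
}
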