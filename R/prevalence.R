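# Internal constructor shared by estimate_prevalence() and
# prevalence_from_summary(): computes the truncated point estimate and the
# truncated Wald interval from the untruncated estimate and its variance.
new_rr_prevalence <- function(estimate_raw, variance, n, observed_rate, level,
                              behaviour = NA_character_, arm = NA_character_,
                              subgroup = NA_character_) {
  stopifnot(level > 0, level < 1)
  if (!is.na(variance) && variance < 0)
    stop_invalid("`variance` must be non-negative")
  estimate <- min(1, max(0, estimate_raw))
  if (is.na(variance)) {
    ci <- c(NA_real_, NA_real_)
  } else {
    z <- stats::qnorm((1 + level) / 2)
    half <- z * sqrt(variance)
    ci <- c(max(0, estimate_raw - half), min(1, estimate_raw + half))
  }
  structure(
    list(behaviour = behaviour, arm = arm, subgroup = subgroup,
         n = n, observed_rate = observed_rate,
         estimate = estimate, estimate_raw = estimate_raw,
         variance = variance, se = sqrt(variance),
         ci_low = ci[1], ci_high = ci[2], level = level),
    class = "rr_prevalence"
  )
}

#' Design-corrected prevalence estimate from randomized responses
#'
#' Inverts the misclassification line of a forced-response design to recover
#' the prevalence of the sensitive behaviour from observed yes/no answers.
#' With (optionally weighted) observed yes-rate \eqn{\hat\lambda}, the
#' estimator is
#' \deqn{\hat\pi = (\hat\lambda - c) / d,}
#' the Horvitz-Thompson-type estimator of the true proportion (the weighted
#' mean reduces to the sample proportion under equal weights). Its variance
#' is estimated by \eqn{\hat V(\hat\lambda)/d^2} with
#' \eqn{\hat V(\hat\lambda) = \hat\lambda(1-\hat\lambda)/(n-1)} under equal
#' weights (simple random sampling, no finite-population correction). The
#' confidence interval is the Wald interval around the untruncated estimate,
#' truncated to \[0, 1\]; the point estimate is likewise truncated, with the
#' raw value kept for diagnostics and for the comparison z-test.
#'
#' @param y Vector of observed 0/1 answers (no missing values, length >= 2).
#' @param design The [rr_design()] under which the answers were collected;
#'   use [direct_design()] for conventional direct questioning, in which case
#'   the estimate is just the (weighted) sample proportion.
#' @param weights Optional positive sampling weights (inverse inclusion
#'   probabilities); default equal weights.
#' @param level Confidence level, default 0.95.
#' @param behaviour,arm,subgroup Optional labels carried into the result.
#' @return An object of class `rr_prevalence` with fields `estimate`,
#'   `estimate_raw`, `variance`, `se`, `ci_low`, `ci_high`, `observed_rate`,
#'   `n`, `level` and the labels.
#' @examples
#' d <- deck_design(8, 8, 24)
#' y <- randomize_response(rbinom(500, 1, 0.6), d, seed = 1)
#' estimate_prevalence(y, d)
#' @seealso [compare_methods()], [subgroup_estimates()]
#' @export
estimate_prevalence <- function(y, design, weights = NULL, level = 0.95,
                                behaviour = NA_character_,
                                arm = NA_character_,
                                subgroup = NA_character_) {
  if (!is_rr_design(design)) stop_invalid("`design` must be an rr_design")
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_invalid("`y` must be 0/1 with no missing values")
  n <- length(y)
  if (n < 2)
    stop_invalid("at least 2 responses are needed (variance undefined for n = ",
                 n, ")")
  w <- weights %||% rep(1, n)
  if (length(w) != n || anyNA(w) || any(w <= 0))
    stop_invalid("`weights` must be positive and match the length of `y`")
  lam <- sum(w * y) / sum(w)
  raw <- (lam - design$c) / design$d
  # Hajek-type variance of the weighted mean; equals lam(1-lam)/(n-1) under
  # equal weights.
  vlam <- n / (n - 1) * sum(w^2 * (y - lam)^2) / sum(w)^2
  new_rr_prevalence(raw, vlam / design$d^2, n, lam, level,
                    behaviour = behaviour, arm = arm, subgroup = subgroup)
}

#' Rebuild a prevalence estimate from its published summary
#'
#' Constructs an `rr_prevalence` object from an already-computed point
#' estimate and variance (e.g. a row of a published estimate table), so that
#' interval truncation and the direct-versus-indirect z-test can be applied
#' to reported numbers without the microdata.
#'
#' @param estimate Untruncated point estimate.
#' @param variance Its estimated variance.
#' @param n Sample size if known.
#' @param level Confidence level, default 0.95.
#' @param behaviour,arm Optional labels.
#' @return An `rr_prevalence` object.
#' @examples
#' # published indirect-arm summary for illicit drug use:
#' prevalence_from_summary(0.9983, 0.0010)  # upper bound truncates to 1
#' @export
prevalence_from_summary <- function(estimate, variance, n = NA_integer_,
                                    level = 0.95,
                                    behaviour = NA_character_,
                                    arm = NA_character_) {
  new_rr_prevalence(estimate, variance, n, NA_real_, level,
                    behaviour = behaviour, arm = arm)
}

#' @export
print.rr_prevalence <- function(x, digits = 4, ...) {
  lab <- paste(stats::na.omit(c(x$behaviour, x$arm, x$subgroup)), collapse = ", ")
  cat("Design-corrected prevalence estimate",
      if (nzchar(lab)) paste0(" (", lab, ")"), "\n", sep = "")
  cat(sprintf("  estimate %s  variance %s  %g%% CI [%s, %s]  n = %s\n",
              fmt_num(x$estimate, digits), fmt_num(x$variance, digits),
              100 * x$level, fmt_num(x$ci_low, digits),
              fmt_num(x$ci_high, digits),
              ifelse(is.na(x$n), "?", x$n)))
  if (!is.na(x$estimate_raw) && (x$estimate_raw < 0 || x$estimate_raw > 1))
    cat(sprintf("  (untruncated estimate %s)\n", fmt_num(x$estimate_raw, digits)))
  invisible(x)
}

#' @export
as.data.frame.rr_prevalence <- function(x, ...) {
  data.frame(behaviour = x$behaviour, arm = x$arm, subgroup = x$subgroup,
             n = x$n, observed_rate = x$observed_rate,
             estimate = x$estimate, estimate_raw = x$estimate_raw,
             variance = x$variance, ci_low = x$ci_low, ci_high = x$ci_high,
             level = x$level, stringsAsFactors = FALSE)
}

#' Subgroup prevalence estimates for one behaviour
#'
#' Splits a respondent table by the categories of one covariate and
#' estimates the behaviour's prevalence separately in each category and
#' questioning arm, each arm corrected with its own design. Categories with
#' fewer than two respondents in an arm are emitted with the raw estimate
#' (when computable) but a flagged, missing variance.
#'
#' @param cohort Respondent data frame with `arm`, the covariate column and
#'   an observed-response column `resp_<behaviour>`.
#' @param behaviour One of `"theft"`, `"drugs"`, `"violence"`, `"speeding"`,
#'   `"arson"` (or any behaviour with a `resp_` column present).
#' @param covariate One of `"education"`, `"marital_status"`,
#'   `"nationality"`, `"crime"`, `"conduct"`.
#' @param designs Named list with elements `direct` and `indirect`, each an
#'   [rr_design()] (defaults: degenerate design and the 40-card deck).
#' @param level Confidence level.
#' @return A data frame of class `rr_prevalence_table`, one row per
#'   category x arm, with the same columns as
#'   `as.data.frame(<rr_prevalence>)` plus `covariate`, `category` and
#'   `flagged`.
#' @export
subgroup_estimates <- function(cohort, behaviour, covariate,
                               designs = list(direct = direct_design(),
                                              indirect = deck_design(8, 8, 24)),
                               level = 0.95) {
  if (!covariate %in% names(covariate_levels()))
    stop_invalid("unknown covariate '", covariate, "'; supported: ",
                 paste(names(covariate_levels()), collapse = ", "))
  col <- paste0("resp_", behaviour)
  if (!col %in% names(cohort))
    stop_invalid("column '", col, "' not found in the cohort")
  if (!covariate %in% names(cohort))
    stop_invalid("column '", covariate, "' not found in the cohort")
  cats <- if (is.factor(cohort[[covariate]])) levels(cohort[[covariate]])
          else unique(as.character(cohort[[covariate]]))
  rows <- list()
  for (cat_i in cats) {
    for (arm_i in c("direct", "indirect")) {
      idx <- cohort[[covariate]] == cat_i & cohort$arm == arm_i
      y <- cohort[[col]][idx]
      n <- length(y)
      if (n >= 2) {
        est <- estimate_prevalence(y, designs[[arm_i]], level = level,
                                   behaviour = behaviour, arm = arm_i,
                                   subgroup = paste0(covariate, "=", cat_i))
        row <- as.data.frame(est)
        row$flagged <- FALSE
      } else {
        lam <- if (n == 1) mean(y) else NA_real_
        raw <- if (n == 1) (lam - designs[[arm_i]]$c) / designs[[arm_i]]$d
               else NA_real_
        row <- data.frame(behaviour = behaviour, arm = arm_i,
                          subgroup = paste0(covariate, "=", cat_i),
                          n = n, observed_rate = lam,
                          estimate = if (is.na(raw)) NA_real_
                                     else min(1, max(0, raw)),
                          estimate_raw = raw, variance = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          level = level, flagged = TRUE,
                          stringsAsFactors = FALSE)
      }
      row$covariate <- covariate
      row$category <- cat_i
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rr_prevalence_table", "data.frame")
  out
}
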