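#' Cohen's h effect size for two proportions
#'
#' \eqn{h = 2(\arcsin\sqrt{p_b} - \arcsin\sqrt{p_a})}, the standard
#' variance-stabilized effect measure for a difference of proportions.
#' Antisymmetric in its arguments.
#'
#' @param p_a,p_b Proportions in \[0, 1\]; vectorized.
#' @return Effect size(s) h.
#' @examples
#' cohens_h(0.5762, 0.8329)  # about 0.57
#' @export
cohens_h <- function(p_a, p_b) {
  if (anyNA(c(p_a, p_b)) || any(c(p_a, p_b) < 0) || any(c(p_a, p_b) > 1))
    stop_invalid("proportions must lie in [0, 1]")
  2 * (asin(sqrt(p_b)) - asin(sqrt(p_a)))
}

#' Test an indirect-versus-direct prevalence contrast
#'
#' The social-desirability-bias signal is a gap between the prevalence
#' recovered by the randomized-response device and the prevalence admitted
#' under direct questioning. The two arms are independent samples, so the
#' contrast is tested with
#' \deqn{z = (\hat\pi_{RR} - \hat\pi_{DQ}) / \sqrt{\hat V_{RR} + \hat V_{DQ}},}
#' computed on the untruncated estimates, with a two-sided standard-normal
#' p-value. Cohen's h on the truncated estimates quantifies the effect.
#'
#' @param direct,indirect `rr_prevalence` objects for the two arms of the
#'   same behaviour.
#' @return Object of class `rr_comparison`: `behaviour`, `z`, `p_value`,
#'   `effect_size_h`, `direction` (sign of indirect minus direct), and the
#'   two estimates.
#' @examples
#' dq <- prevalence_from_summary(0.5762, 0.0005, behaviour = "theft")
#' rr <- prevalence_from_summary(0.8329, 0.0014, behaviour = "theft")
#' compare_methods(dq, rr)  # z about 5.89, p < 0.001
#' @export
compare_methods <- function(direct, indirect) {
  if (!inherits(direct, "rr_prevalence") || !inherits(indirect, "rr_prevalence"))
    stop_invalid("both arguments must be rr_prevalence objects")
  if (!is.na(direct$behaviour) && !is.na(indirect$behaviour) &&
      direct$behaviour != indirect$behaviour)
    stop_invalid("estimates describe different behaviours ('",
                 direct$behaviour, "' vs '", indirect$behaviour, "')")
  if (is.na(direct$variance) || is.na(indirect$variance))
    stop_invalid("both estimates must carry variances")
  vsum <- direct$variance + indirect$variance
  if (vsum <= 0)
    stop_invalid("both variances are zero; the z statistic is undefined")
  diff <- indirect$estimate_raw - direct$estimate_raw
  z <- diff / sqrt(vsum)
  structure(
    list(behaviour = if (!is.na(direct$behaviour)) direct$behaviour
                     else indirect$behaviour,
         z = z, p_value = 2 * stats::pnorm(-abs(z)),
         effect_size_h = cohens_h(direct$estimate, indirect$estimate),
         direction = sign(diff), direct = direct, indirect = indirect),
    class = "rr_comparison"
  )
}

#' @export
print.rr_comparison <- function(x, digits = 4, ...) {
  cat("Direct vs indirect questioning",
      if (!is.na(x$behaviour)) paste0(" (", x$behaviour, ")"), "\n", sep = "")
  cat(sprintf("  direct %s, indirect %s\n",
              fmt_num(x$direct$estimate, digits),
              fmt_num(x$indirect$estimate, digits)))
  cat(sprintf("  z = %s, two-sided p %s, Cohen's h = %s\n",
              fmt_num(x$z, 3),
              ifelse(x$p_value < 0.001, "< 0.001",
                     paste("=", fmt_num(x$p_value, digits))),
              fmt_num(x$effect_size_h, 3)))
  invisible(x)
}

#' Prevalence and comparison report for all behaviours
#'
#' Estimates every behaviour's prevalence in both questioning arms and tests
#' each direct-versus-indirect contrast, producing the report that summarizes
#' a whole survey: two rows (direct, indirect) per behaviour with estimate,
#' variance, truncated confidence bounds, the contrast's p-value and Cohen's
#' h.
#'
#' @param cohort Respondent data frame with `arm` and `resp_<behaviour>`
#'   columns.
#' @param designs Named list with `direct` and `indirect` [rr_design()]s.
#' @param behaviours Behaviours to report, in fixed row order; behaviours
#'   whose response column is absent are dropped with a warning.
#' @param level Confidence level.
#' @return Data frame of class `rr_comparison_table`: columns `behaviour`,
#'   `method`, `n`, `estimate`, `variance`, `ci_low`, `ci_high`, `p_value`,
#'   `effect_size_h`.
#' @export
compare_all <- function(cohort,
                        designs = list(direct = direct_design(),
                                       indirect = deck_design(8, 8, 24)),
                        behaviours = c("theft", "drugs", "violence",
                                       "speeding", "arson"),
                        level = 0.95) {
  if (!"arm" %in% names(cohort)) stop_invalid("cohort has no `arm` column")
  for (a in c("direct", "indirect"))
    if (sum(cohort$arm == a) < 2)
      stop_invalid("the ", a, " arm is empty or has fewer than 2 respondents")
  rows <- list()
  for (b in behaviours) {
    col <- paste0("resp_", b)
    if (!col %in% names(cohort)) {
      warning("behaviour '", b, "' has no response column; row omitted",
              call. = FALSE)
      next
    }
    ests <- lapply(c(direct = "direct", indirect = "indirect"), function(a) {
      estimate_prevalence(cohort[[col]][cohort$arm == a], designs[[a]],
                          level = level, behaviour = b, arm = a)
    })
    cmp <- compare_methods(ests$direct, ests$indirect)
    for (a in c("direct", "indirect")) {
      e <- ests[[a]]
      rows[[length(rows) + 1L]] <- data.frame(
        behaviour = b, method = a, n = e$n, estimate = e$estimate,
        variance = e$variance, ci_low = e$ci_low, ci_high = e$ci_high,
        p_value = cmp$p_value, effect_size_h = cmp$effect_size_h,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rr_comparison_table", "data.frame")
  out
}
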