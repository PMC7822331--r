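#' Forced-response randomization designs
#'
#' A forced-response design offers each respondent a randomization device
#' (here, a deck of cards) that with probability `p_forced_yes` forces the
#' answer "yes", with probability `p_forced_no` forces "no", and with the
#' remaining probability `p_genuine` requests the truthful answer. The device
#' induces an affine misclassification line between the true prevalence
#' \eqn{\pi} of the sensitive behaviour and the observed yes-probability
#' \eqn{\lambda}:
#' \deqn{\lambda = c + d\,\pi, \quad c = p_{forced\,yes}, \; d = p_{genuine}.}
#' Everything downstream (prevalence estimation, regression) consumes the
#' design only through `(c, d)`.
#'
#' @param p_forced_yes Probability of a forced "yes" card.
#' @param p_forced_no Probability of a forced "no" card.
#' @param p_genuine Probability of a genuine-answer card; defaults to the
#'   complement. Must be strictly positive or the design carries no
#'   information and the prevalence estimator is undefined.
#' @return An object of class `rr_design`: a list with elements
#'   `p_forced_yes`, `p_forced_no`, `p_genuine`, `c`, `d`.
#' @examples
#' rr_design(0.2, 0.2)          # the 40-card Spanish-deck device
#' direct_design()              # degenerate design = direct questioning
#' @seealso [deck_design()], [response_probability()], [estimate_prevalence()]
#' @export
rr_design <- function(p_forced_yes, p_forced_no,
                      p_genuine = 1 - p_forced_yes - p_forced_no) {
  p <- c(p_forced_yes, p_forced_no, p_genuine)
  if (!is.numeric(p) || length(p) != 3L || anyNA(p))
    stop_invalid("design probabilities must be three non-missing numbers")
  if (any(p < 0) || any(p > 1))
    stop_invalid("design probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12)
    stop_invalid("design probabilities must sum to 1 (tolerance 1e-12), got ",
                 format(sum(p), digits = 15))
  if (p_genuine <= 0)
    stop_invalid("invalid design: the genuine-answer probability is 0, ",
                 "so the prevalence estimator is undefined")
  structure(
    list(p_forced_yes = p_forced_yes, p_forced_no = p_forced_no,
         p_genuine = p_genuine, c = p_forced_yes, d = p_genuine),
    class = "rr_design"
  )
}

#' @export
print.rr_design <- function(x, ...) {
  cat("Forced-response randomization design\n")
  cat(sprintf("  P(forced yes) = %.4f, P(forced no) = %.4f, P(genuine) = %.4f\n",
              x$p_forced_yes, x$p_forced_no, x$p_genuine))
  cat(sprintf("  misclassification line: lambda = %.4f + %.4f * pi\n", x$c, x$d))
  invisible(x)
}

is_rr_design <- function(x) inherits(x, "rr_design")

#' Derive a forced-response design from a physical card deck
#'
#' Converts card counts into exact device probabilities. The motivating
#' survey used a 40-card Spanish deck: cards numbered 1-2 in each of four
#' suits force "yes" (8 cards), 3-4 force "no" (8 cards), and 5-7 plus the
#' three figures request the genuine answer (24 cards), giving
#' probabilities (0.2, 0.2, 0.6).
#'
#' @param forced_yes,forced_no,genuine Non-negative integer card counts;
#'   `genuine` must be at least 1.
#' @param total Total deck size; defaults to the sum of the three counts and
#'   is validated against it.
#' @return An [rr_design()] object with card-count-fraction probabilities.
#' @examples
#' deck_design(8, 8, 24)   # (0.2, 0.2, 0.6), c = 0.2, d = 0.6
#' @export
deck_design <- function(forced_yes, forced_no, genuine,
                        total = forced_yes + forced_no + genuine) {
  counts <- c(forced_yes, forced_no, genuine, total)
  if (!is.numeric(counts) || anyNA(counts) || any(counts != round(counts)))
    stop_invalid("card counts must be integers")
  if (any(counts[1:3] < 0) || total <= 0)
    stop_invalid("card counts must be non-negative and the deck non-empty")
  if (forced_yes + forced_no + genuine != total)
    stop_invalid("card counts (", forced_yes, " + ", forced_no, " + ", genuine,
                 ") do not sum to the deck size ", total)
  if (genuine < 1)
    stop_invalid("invalid design: a deck with no genuine-answer cards ",
                 "identifies nothing (the estimator is undefined)")
  rr_design(forced_yes / total, forced_no / total, genuine / total)
}

#' The degenerate design representing direct questioning
#'
#' Direct questioning is the forced-response design with no forced cards:
#' `(c, d) = (0, 1)`, so the observed yes-probability equals the true
#' prevalence (up to any reporting bias in the respondents themselves).
#'
#' @return An [rr_design()] with probabilities (0, 0, 1).
#' @export
direct_design <- function() rr_design(0, 0, 1)

#' Observed yes-probability implied by a design and a true prevalence
#'
#' Evaluates the misclassification line \eqn{\lambda = c + d\pi}.
#'
#' @param design An [rr_design()].
#' @param prevalence True prevalence(s) \eqn{\pi} in \[0, 1\]; vectorized.
#' @return Observed yes-probabilities, in \eqn{[c, c + d]}.
#' @examples
#' d <- deck_design(8, 8, 24)
#' response_probability(d, c(0, 0.8329, 1))  # 0.2, 0.69974, 0.8
#' @export
response_probability <- function(design, prevalence) {
  if (!is_rr_design(design)) stop_invalid("`design` must be an rr_design")
  if (anyNA(prevalence) || any(prevalence < 0) || any(prevalence > 1))
    stop_invalid("`prevalence` must lie in [0, 1]")
  design$c + design$d * prevalence
}

#' Pass true statuses through the randomization device
#'
#' Simulates one card draw per respondent (with replacement, as the card is
#' returned to the deck): a forced-yes card yields 1, a forced-no card yields
#' 0, a genuine card yields the true status. Draws are independent across
#' respondents and items.
#'
#' @param true_status Vector of 0/1 true statuses.
#' @param design An [rr_design()].
#' @param seed Optional integer seed (see [with_seed()]); the caller's RNG
#'   state is restored afterwards.
#' @return Integer vector of observed 0/1 answers.
#' @export
randomize_response <- function(true_status, design, seed = NULL) {
  if (!is_rr_design(design)) stop_invalid("`design` must be an rr_design")
  if (anyNA(true_status) || !all(true_status %in% c(0, 1)))
    stop_invalid("`true_status` must be 0/1 with no missing values")
  with_seed(seed, {
    u <- stats::runif(length(true_status))
    ifelse(u < design$p_forced_yes, 1L,
           ifelse(u < design$p_forced_yes + design$p_forced_no, 0L,
                  as.integer(true_status)))
  })
}

#' Closed-form variance of the forced-response prevalence estimator
#'
#' Sampling variance of \eqn{\hat\pi = (\hat\lambda - c)/d} under simple
#' random sampling with true prevalence \eqn{\pi}:
#' \eqn{\lambda(1-\lambda) / ((n-1) d^2)}. For the degenerate direct design
#' this reduces to the binomial proportion variance; for any genuine
#' forced-response device (`d < 1`) it is strictly larger at equal `n` —
#' the price paid for respondent privacy.
#'
#' @param design An [rr_design()].
#' @param prevalence True prevalence \eqn{\pi}; vectorized.
#' @param n Sample size (>= 2).
#' @return Variance of the prevalence estimator.
#' @export
prevalence_variance <- function(design, prevalence, n) {
  if (n < 2) stop_invalid("`n` must be at least 2")
  lam <- response_probability(design, prevalence)
  lam * (1 - lam) / ((n - 1) * design$d^2)
}
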