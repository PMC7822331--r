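#' Total severity score of the Yale-Brown obsessive-compulsive scale
#'
#' Sums the ten severity items (time spent, interference, distress,
#' resistance and control, each rated for obsessions and compulsions on a
#' 0-4 scale) into the 0-40 total used as the obsessive-compulsive covariate
#' in the regression models.
#'
#' @param items Integer vector of exactly ten item scores, each in 0-4.
#' @return Integer total in 0-40.
#' @examples
#' ybocs_total(c(4, 4, 4, 4, 0, 0, 0, 0, 0, 0))  # 16
#' @export
ybocs_total <- function(items) {
  if (length(items) != 10L)
    stop_invalid("the severity scale has exactly ten items, got ", length(items))
  if (anyNA(items) || !all(items %in% 0:4))
    stop_invalid("every severity item must be an integer in 0-4")
  as.integer(sum(items))
}

#' Severity category of a Yale-Brown total score
#'
#' Maps totals to the published bands: low (8-15), moderate (16-23),
#' severe (24-31), very severe (32-40), all boundaries inclusive. Totals of
#' 0-7 fall below the lowest published band and are labelled
#' `"subthreshold"`, a label defined by this package rather than the scale.
#'
#' @param total Integer total score(s) in 0-40; vectorized.
#' @return Factor with levels subthreshold < low < moderate < severe <
#'   very severe.
#' @examples
#' ybocs_category(c(0, 15, 16, 32))
#' @export
ybocs_category <- function(total) {
  if (anyNA(total) || !all(total == round(total)))
    stop_invalid("`total` must be whole numbers with no missing values")
  if (any(total < 0) || any(total > 40))
    stop_invalid("`total` must lie in 0-40")
  cut(total, breaks = c(-1, 7, 15, 23, 31, 40),
      labels = c("subthreshold", "low", "moderate", "severe", "very severe"),
      ordered_result = TRUE)
}
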