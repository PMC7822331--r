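# Required columns of the respondent CSV schema, in canonical order.
respondent_columns <- function(behaviours = behaviour_names()) {
  c("id", "arm", names(covariate_levels()),
    "age", "sentence_months", "oc_score",
    paste0("resp_", behaviours))
}

#' Write respondents to the documented CSV schema
#'
#' Columns: `id, arm, education, marital_status, nationality, crime,
#' conduct, age, sentence_months, oc_score, resp_theft ... resp_arson`,
#' plus any `true_*` columns present (synthetic cohorts only). UTF-8,
#' header required.
#'
#' @param cohort Respondent data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_respondents <- function(cohort, path) {
  behaviours <- sub("^resp_", "", grep("^resp_", names(cohort), value = TRUE))
  cols <- c(respondent_columns(behaviours),
            grep("^true_", names(cohort), value = TRUE))
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop_invalid("cohort lacks column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(cohort[cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a respondent CSV
#'
#' Checks the header before parsing rows, then validates every record:
#' categorical labels are matched case-insensitively against the documented
#' vocabularies, observed answers must be 0/1 with no missing values, age
#' must lie in 18-55 (the survey's inclusion criterion), sentence length
#' must be non-negative and the obsessive-compulsive score in 0-40.
#' Validation errors name the offending row and column. When the optional
#' item columns `yboc_item_1 ... yboc_item_10` are present, the severity
#' total is recomputed with [ybocs_total()]; mismatching `oc_score` entries
#' are reported and replaced.
#'
#' @param path CSV file in the schema written by [write_respondents()].
#' @param behaviours Behaviours whose response columns are required.
#' @return Validated respondent data frame with factor covariates.
#' @export
read_respondents <- function(path, behaviours = behaviour_names()) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  required <- respondent_columns(behaviours)
  missing <- setdiff(required, header)
  if (length(missing))
    stop_invalid("schema error: header lacks column(s): ",
                 paste(missing, collapse = ", "))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  problems <- character()
  note <- function(row, col, msg)
    problems <<- c(problems, sprintf("row %d, column %s: %s", row, col, msg))

  arm_lab <- tolower(trimws(df$arm))
  bad <- which(!arm_lab %in% c("direct", "indirect"))
  for (i in bad) note(i, "arm", paste0("unknown label '", df$arm[i], "'"))
  df$arm <- factor(arm_lab, levels = c("direct", "indirect"))

  vocab <- covariate_levels()
  for (cv in names(vocab)) {
    lab <- tolower(trimws(df[[cv]]))
    bad <- which(!lab %in% vocab[[cv]])
    for (i in bad) note(i, cv, paste0("unknown label '", df[[cv]][i], "'"))
    df[[cv]] <- factor(lab, levels = vocab[[cv]])
  }
  for (b in behaviours) {
    col <- paste0("resp_", b)
    bad <- which(is.na(df[[col]]) | !df[[col]] %in% c(0, 1))
    for (i in bad) note(i, col, paste0("non-binary response '", df[[col]][i], "'"))
  }
  bad <- which(is.na(df$age) | df$age < 18 | df$age > 55)
  for (i in bad) note(i, "age", paste0("outside 18-55: '", df$age[i], "'"))
  bad <- which(is.na(df$sentence_months) | df$sentence_months < 0)
  for (i in bad) note(i, "sentence_months",
                      paste0("negative or missing: '", df$sentence_months[i], "'"))
  bad <- which(is.na(df$oc_score) | df$oc_score < 0 | df$oc_score > 40)
  for (i in bad) note(i, "oc_score", paste0("outside 0-40: '", df$oc_score[i], "'"))

  if (length(problems))
    stop_invalid("invalid respondent file:\n  ",
                 paste(utils::head(problems, 20), collapse = "\n  "),
                 if (length(problems) > 20)
                   paste0("\n  ... and ", length(problems) - 20, " more"))

  item_cols <- paste0("yboc_item_", 1:10)
  if (all(item_cols %in% names(df))) {
    recomputed <- apply(as.matrix(df[item_cols]), 1, ybocs_total)
    mism <- which(recomputed != df$oc_score)
    if (length(mism))
      message(length(mism), " oc_score value(s) disagree with the item sums ",
              "(rows ", paste(utils::head(mism, 10), collapse = ", "),
              "); recomputed totals used")
    df$oc_score <- recomputed
  }
  df
}

#' Read a pipeline configuration file
#'
#' YAML with blocks `cohort` (arguments of [cohort_config()]), `design`
#' (either `deck: {forced_yes, forced_no, genuine}` or
#' `probabilities: [p_yes, p_no, p_genuine]`), `analysis` (`level`,
#' `behaviours`, `subgroups`, `regression: {behaviours, terms, stepwise}`),
#' `output` (`dir`, `digits`), optional `input` (respondent CSV to analyse
#' instead of simulating) and `seed`.
#'
#' @param path YAML file path.
#' @return Config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg)
}

as_pipeline_config <- function(cfg) {
  cfg$analysis <- cfg$analysis %||% list()
  cfg$analysis$level <- cfg$analysis$level %||% 0.95
  if (cfg$analysis$level <= 0 || cfg$analysis$level >= 1)
    stop_invalid("analysis$level must lie in (0, 1)")
  cfg$analysis$behaviours <- cfg$analysis$behaviours %||% behaviour_names()
  cfg$output <- cfg$output %||% list()
  cfg$output$digits <- cfg$output$digits %||% 4
  if (cfg$output$digits < 1) stop_invalid("output$digits must be >= 1")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop_invalid("input file does not exist: ", cfg$input)
  structure(cfg, class = "pipeline_config")
}

# Build the indirect-arm design from a config's design block.
config_design <- function(cfg) {
  dz <- cfg$design
  if (is.null(dz)) return(deck_design(8, 8, 24))
  if (!is.null(dz$deck))
    return(deck_design(dz$deck$forced_yes, dz$deck$forced_no, dz$deck$genuine))
  if (!is.null(dz$probabilities)) {
    p <- dz$probabilities
    return(rr_design(p[[1]], p[[2]], p[[3]]))
  }
  stop_invalid("design block must contain `deck` or `probabilities`")
}
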