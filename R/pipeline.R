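# Write a data frame as a fixed-decimal TSV (deterministic byte-for-byte
# given identical numbers).
write_report <- function(df, path, digits = 4) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !names(out)[j] %in% c("n", "id", "step"))
      out[[j]] <- fmt_num(out[[j]], digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Cohort summary in the style of a sociodemographic table: category counts
# plus mean (sd) of the numeric covariates.
cohort_summary <- function(cohort, digits = 4) {
  rows <- list()
  for (cv in names(covariate_levels())) {
    if (!cv %in% names(cohort)) next
    tab <- table(cohort[[cv]])
    rows[[length(rows) + 1L]] <-
      data.frame(variable = cv, category = names(tab),
                 value = as.character(as.vector(tab)),
                 stringsAsFactors = FALSE)
  }
  for (num in c("age", "sentence_months", "oc_score")) {
    if (!num %in% names(cohort)) next
    rows[[length(rows) + 1L]] <-
      data.frame(variable = num, category = "mean (sd)",
                 value = sprintf("%s (%s)",
                                 fmt_num(mean(cohort[[num]]), 2),
                                 fmt_num(stats::sd(cohort[[num]]), 3)),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the survey analysis pipeline
#'
#' Executes the requested stages in order — `simulate` (or load an input
#' respondent file), `estimate`, `compare`, `regress`, `report` — under one
#' master seed that spawns independent per-stage substreams, and writes
#' delimited reports: a sociodemographic cohort summary, a
#' prevalence/comparison table (two rows per behaviour), and one regression
#' report per requested behaviour with AIC and Pearson lines. Running the
#' same configuration and seed twice produces byte-identical outputs.
#'
#' @param config A `pipeline_config`, a YAML file path, or a plain list in
#'   the same shape.
#' @param seed Master seed; overrides the config's `seed`.
#' @param out_dir Output directory; overrides `output$dir` (default
#'   `"results"`).
#' @param stages Character subset of
#'   `c("simulate", "estimate", "compare", "regress", "report")`; stages
#'   always run in canonical order.
#' @param verbose Log stage timings and seeds with `message()`.
#' @return Invisible list with the cohort and every computed table, plus the
#'   paths written.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL,
                         stages = c("simulate", "estimate", "compare",
                                    "regress", "report"),
                         verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- as_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  master <- seed %||% config$seed
  seeds <- derive_seeds(master, 2)
  out_dir <- out_dir %||% config$output$dir %||% "results"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  digits <- config$output$digits
  design <- config_design(config)
  designs <- list(direct = direct_design(), indirect = design)
  level <- config$analysis$level
  bundle <- list(paths = character(), seed = master)

  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    if (verbose)
      message(sprintf("stage %-9s done in %.2fs", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  # -- cohort: simulate or load -------------------------------------------
  cohort <- NULL
  if (!is.null(config$input)) {
    cohort <- run_stage("load", read_respondents(config$input,
                                                 config$analysis$behaviours))
  } else if ("simulate" %in% stages ||
             any(c("estimate", "compare", "regress", "report") %in% stages)) {
    cohort <- run_stage("simulate", {
      args <- config$cohort %||% list()
      args$behaviours <- args$behaviours %||% config$analysis$behaviours
      args$seed <- seeds[[1]]
      simulate_survey(do.call(cohort_config, args), design)
    })
    if ("simulate" %in% stages) {
      p <- file.path(out_dir, "cohort.csv")
      write_respondents(cohort, p)
      bundle$paths <- c(bundle$paths, p)
    }
    if (verbose && !is.null(master))
      message("master seed ", master, "; stage seeds ",
              paste(unlist(seeds), collapse = ", "))
  }
  bundle$cohort <- cohort

  # -- estimate / compare -------------------------------------------------
  if ("estimate" %in% stages || "compare" %in% stages) {
    tab <- run_stage("estimate",
                     compare_all(cohort, designs,
                                 behaviours = config$analysis$behaviours,
                                 level = level))
    if (!"compare" %in% stages) tab$p_value <- tab$effect_size_h <- NULL
    bundle$prevalence <- tab
    p <- file.path(out_dir, if ("compare" %in% stages)
      "prevalence_comparison.tsv" else "prevalence_estimates.tsv")
    write_report(tab, p, digits)
    bundle$paths <- c(bundle$paths, p)

    subs <- config$analysis$subgroups
    if (length(subs)) {
      bundle$subgroups <- run_stage("subgroups", {
        res <- list()
        for (cv in subs) for (b in config$analysis$behaviours)
          res[[paste(b, cv, sep = ".")]] <-
            subgroup_estimates(cohort, b, cv, designs, level)
        res
      })
      for (nm in names(bundle$subgroups)) {
        p <- file.path(out_dir, paste0("subgroup_", nm, ".tsv"))
        write_report(bundle$subgroups[[nm]], p, digits)
        bundle$paths <- c(bundle$paths, p)
      }
    }
  }

  # -- regress ------------------------------------------------------------
  if ("regress" %in% stages) {
    reg <- config$analysis$regression %||% list()
    reg_beh <- reg$behaviours %||% c("theft", "drugs", "arson")
    terms <- reg$terms %||% c("arm", "education", "marital_status", "crime",
                              "conduct", "age", "sentence_months", "oc_score")
    do_step <- isTRUE(reg$stepwise %||% TRUE)
    bundle$regression <- run_stage("regress", {
      fits <- list()
      for (b in reg_beh) {
        f <- stats::reformulate(terms, response = paste0("resp_", b))
        environment(f) <- environment()
        fit <- rr_glm(f, cohort, designs, arm = "arm")
        if (do_step) fit <- step_rr_glm(fit)
        fits[[b]] <- fit
      }
      fits
    })
    for (b in names(bundle$regression)) {
      fit <- bundle$regression[[b]]
      p <- file.path(out_dir, paste0("regression_", b, ".tsv"))
      write_report(odds_ratio_table(fit), p, digits)
      gof <- suppressMessages(suppressWarnings(pearson_gof(fit)))
      cat(sprintf("AIC\t%.2f\nPearson\t%.5f\n", fit$aic, gof$p.value),
          file = p, append = TRUE)
      bundle$paths <- c(bundle$paths, p)
    }
  }

  # -- report -------------------------------------------------------------
  if ("report" %in% stages && !is.null(cohort)) {
    p <- file.path(out_dir, "cohort_summary.tsv")
    write_report(cohort_summary(cohort, digits), p, digits)
    bundle$paths <- c(bundle$paths, p)
  }

  invisible(bundle)
}
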