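# Staged pipeline: simulate -> clean -> cohort -> outcomes -> fit -> report.
# Each stage reads its inputs from `outdir` and writes its outputs there,
# so stages can be re-run individually; a manifest records configuration
# hash, seed, stage timings, and every file written with its row count.

pipeline_stages <- c("simulate", "clean", "cohort", "outcomes", "fit",
                     "report")

stage_requires <- list(
  clean = c(fills = "fills.csv"),
  cohort = c(fills_clean = "fills_clean.csv", spans = "spans.csv",
             claims = "claims.csv", deaths = "deaths.csv",
             demographics = "demographics.csv"),
  outcomes = c(cohort = "cohort.csv", fills_clean = "fills_clean.csv",
               spans = "spans.csv", claims = "claims.csv",
               deaths = "deaths.csv"),
  fit = c(cohort = "cohort.csv", chronic = "chronic_use.csv",
          survival = "survival.csv", secondary = "secondary.csv"),
  report = c(cohort = "cohort.csv", chronic = "chronic_use.csv",
             survival = "survival.csv"))

read_stage_input <- function(outdir, files, stage) {
  paths <- file.path(outdir, files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing upstream artifact '", files[missing][1],
         "'; run stage '", pipeline_stage_of(files[missing][1]),
         "' first", call. = FALSE)
  }
  out <- lapply(paths, function(p) {
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  })
  names(out) <- names(files)
  out
}

pipeline_stage_of <- function(file) {
  producers <- c("fills.csv" = "simulate", "spans.csv" = "simulate",
                 "claims.csv" = "simulate", "deaths.csv" = "simulate",
                 "demographics.csv" = "simulate",
                 "fills_clean.csv" = "clean", "cohort.csv" = "cohort",
                 "chronic_use.csv" = "outcomes", "survival.csv" = "outcomes",
                 "secondary.csv" = "outcomes")
  unname(producers[file])
}

write_output <- function(x, outdir, file, manifest) {
  path <- file.path(outdir, file)
  readr::write_csv(x, path, progress = FALSE)
  manifest$files[[file]] <- list(file = file, rows = nrow(x))
  manifest
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order: `simulate` (synthetic registry),
#' `clean` (PDMP cleaning), `cohort` (index events, enrollment filter,
#' covariates), `outcomes` (chronic use, overdose, survival, secondary),
#' `fit` (all models), `report` (balance and outcome tables). All artifacts
#' are CSV/JSON in `outdir`; re-running with an unchanged config and seed
#' reproduces the outputs byte for byte.
#'
#' @param config A [sim_config()]; its `models` element (optional list with
#'   `random_effect`, `include_mme`) controls the fit stage.
#' @param outdir Output directory.
#' @param stages Subset of
#'   `c("simulate","clean","cohort","outcomes","fit","report")`.
#' @param seed Overrides `config$seed` when given.
#' @return The run manifest (invisibly written to `manifest.json`):
#'   config hash, seed, stage timings, and file inventory with row counts.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         stages = pipeline_stages, seed = NULL) {
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  manifest <- list(
    package_version = as.character(utils::packageVersion("opioidcohort")),
    config_hash = hash_config(config), seed = config$seed,
    stages = list(), files = list())
  mme_tab <- default_mme_table()
  code_set <- default_code_set()
  mcfg <- config$models %||% list()
  random_effect <- mcfg$random_effect %||% "on"
  include_mme <- if (is.null(mcfg$include_mme)) TRUE else mcfg$include_mme

  for (stage in pipeline_stages[pipeline_stages %in% stages]) {
    t0 <- proc.time()[["elapsed"]]
    if (stage == "simulate") {
      pop <- generate_population(config)
      for (tb in c("fills", "spans", "claims", "deaths", "demographics")) {
        manifest <- write_output(pop[[tb]], outdir, paste0(tb, ".csv"),
                                 manifest)
      }
      manifest <- write_output(pop$truth, outdir, "truth.csv", manifest)
    } else if (stage == "clean") {
      inp <- read_stage_input(outdir, stage_requires$clean, stage)
      inp$fills$fill_date <- as.Date(inp$fills$fill_date)
      cl <- clean_fills(inp$fills)
      manifest <- write_output(cl$fills, outdir, "fills_clean.csv", manifest)
      manifest <- write_output(cl$removal_log, outdir, "removal_log.csv",
                               manifest)
    } else if (stage == "cohort") {
      inp <- read_stage_input(outdir, stage_requires$cohort, stage)
      idx <- find_index_events(inp$fills_clean, inp$claims, code_set)
      flt <- apply_enrollment_filter(idx, inp$spans, inp$deaths)
      cohort <- categorize(flt$kept, inp$demographics, inp$spans, mme_tab)
      manifest <- write_output(cohort, outdir, "cohort.csv", manifest)
      manifest <- write_output(flt$excluded, outdir, "exclusions.csv",
                               manifest)
    } else if (stage == "outcomes") {
      inp <- read_stage_input(outdir, stage_requires$outcomes, stage)
      idx <- restore_cohort(inp$cohort)
      ie <- index_events_from_cohort(idx, inp$fills_clean)
      chron <- compute_chronic_use(inp$fills_clean, ie, inp$deaths)
      odev <- detect_overdose(inp$claims, inp$deaths, ie, code_set)
      surv <- compute_survival(ie, inp$spans, odev, inp$deaths,
                               as.Date(config$window$study_end))
      secondary <- compute_secondary(inp$fills_clean, ie, mme_tab)
      manifest <- write_output(chron, outdir, "chronic_use.csv", manifest)
      manifest <- write_output(odev, outdir, "overdose_events.csv", manifest)
      manifest <- write_output(surv, outdir, "survival.csv", manifest)
      manifest <- write_output(secondary, outdir, "secondary.csv", manifest)
    } else if (stage == "fit") {
      inp <- read_stage_input(outdir, stage_requires$fit, stage)
      cohort <- restore_cohort(inp$cohort)
      reports <- list(
        chronic = fit_chronic_logistic(cohort, inp$chronic,
                                       random_effect = random_effect,
                                       include_mme = include_mme),
        overdose = fit_overdose_cox(cohort, inp$survival),
        cumulative_mme = fit_cumulative_zinb(cohort, inp$secondary),
        switch = fit_switch_logistic(cohort, inp$secondary,
                                     random_effect = random_effect))
      json <- lapply(reports, unclass)
      jsonlite::write_json(json, file.path(outdir, "model_reports.json"),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
      manifest$files[["model_reports.json"]] <-
        list(file = "model_reports.json", rows = length(reports))
    } else if (stage == "report") {
      inp <- read_stage_input(outdir, stage_requires$report, stage)
      cohort <- restore_cohort(inp$cohort)
      tabs <- render_tables(cohort, inp$chronic, inp$survival)
      manifest <- write_output(tabs$balance, outdir, "table_balance.csv",
                               manifest)
      manifest <- write_output(tabs$chronic, outdir, "table_chronic.csv",
                               manifest)
      manifest <- write_output(tabs$overdose, outdir, "table_overdose.csv",
                               manifest)
    }
    manifest$stages[[stage]] <-
      round(proc.time()[["elapsed"]] - t0, 3)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# CSV round-trips drop factor levels; restore them.
restore_cohort <- function(cohort) {
  cohort$index_date <- as.Date(cohort$index_date)
  for (v in names(cohort_levels)) {
    if (v %in% names(cohort)) {
      cohort[[v]] <- factor(as.character(cohort[[v]]),
                            levels = cohort_levels[[v]])
    }
  }
  cohort
}

# Rebuild the index-event columns the outcome functions need from the
# cohort table plus the cleaned fills (drug_base of the index fill).
index_events_from_cohort <- function(cohort, fills) {
  fills$fill_date <- as.Date(fills$fill_date)
  idx <- dplyr::inner_join(
    cohort[, c("patient_id", "index_date")],
    fills[, c("patient_id", "fill_date", "drug_base")],
    by = dplyr::join_by("patient_id", "index_date" == "fill_date")) %>%
    dplyr::distinct(.data$patient_id, .keep_all = TRUE)
  idx
}

#' Render report tables
#'
#' Builds the covariate balance table (counts, within-group percentages,
#' standardized differences by index drug) and outcome tables (counts and
#' row percentages of chronic use and overdose by covariate level, with
#' adjusted ratios merged in when model reports are supplied).
#'
#' @param cohort Cohort table.
#' @param chronic Chronic-use results.
#' @param survival_records Survival records.
#' @param reports Optional named list of `model_report`s (`chronic`,
#'   `overdose`) whose ratios/CIs are merged into the outcome tables.
#' @return List of tibbles: `balance`, `chronic`, `overdose`.
#' @export
render_tables <- function(cohort, chronic, survival_records,
                          reports = NULL) {
  balance <- balance_table(cohort)
  chronic_tab <- outcome_count_table(
    cohort, tibble::tibble(patient_id = chronic$patient_id,
                           outcome = chronic$chronic_primary),
    reports$chronic)
  overdose_tab <- outcome_count_table(
    cohort, tibble::tibble(patient_id = survival_records$patient_id,
                           outcome = survival_records$event),
    reports$overdose)
  list(balance = balance, chronic = chronic_tab, overdose = overdose_tab)
}

outcome_count_table <- function(cohort, outcome, report = NULL) {
  data <- dplyr::inner_join(cohort, outcome, by = "patient_id")
  rows <- lapply(default_covariates, function(v) {
    lv <- levels(factor(data[[v]]))
    k1 <- unname(vapply(lv, function(l) sum(data[[v]] == l & !data$outcome,
                                            na.rm = TRUE), numeric(1)))
    k2 <- unname(vapply(lv, function(l) sum(data[[v]] == l & data$outcome,
                                            na.rm = TRUE), numeric(1)))
    tibble::tibble(covariate = v, level = lv, n_without = k1, n_with = k2,
                   row_pct = 100 * k2 / pmax(1e-12, k1 + k2))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(report)) {
    est <- report$estimates[, c("term", "level", "ratio", "ci_low",
                                "ci_high", "p_value")]
    out <- dplyr::left_join(out, est,
                            by = c("covariate" = "term", "level"))
  }
  out
}
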