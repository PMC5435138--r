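## ---- CSV schemas -----------------------------------------------------

## Coerce a character column to numeric, failing loudly with file/row/column
## context; empty fields are missing values.
coerce_numeric_col <- function(x, col, file) {
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("%s: column '%s' has non-numeric value \"%s\" in row %d",
                 file, col, x[bad[1]], bad[1]))
  }
  out
}

check_required_columns <- function(df, required, file) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0 && identical(required, OXIMETRY_COLUMNS)) {
    warning(sprintf("%s: ignoring unknown column(s): %s", file,
                    paste(extra, collapse = ", ")))
  }
  invisible(df)
}

OXIMETRY_COLUMNS <- c("patient_id", "minute", "spo2", "o2_flag", "source")

#' Read / write the long-format oximetry CSV
#'
#' Columns: `patient_id`, `minute` (0-based integer), `spo2` (percent,
#' empty = missing), `o2_flag` (0/1), `source` (`continuous` or
#' `manual_room_air`). Schema violations raise errors naming the file, row
#' and column.
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_oximetry_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  check_required_columns(df, OXIMETRY_COLUMNS, path)
  df <- df[OXIMETRY_COLUMNS]
  df$minute <- as.integer(coerce_numeric_col(df$minute, "minute", path))
  df$spo2 <- coerce_numeric_col(df$spo2, "spo2", path)
  df$o2_flag <- coerce_numeric_col(df$o2_flag, "o2_flag", path) == 1
  bad_src <- which(!df$source %in% c("continuous", "manual_room_air"))
  if (length(bad_src) > 0) {
    stop(sprintf("%s: column 'source' has invalid value \"%s\" in row %d",
                 path, df$source[bad_src[1]], bad_src[1]))
  }
  df
}

#' @rdname read_oximetry_csv
#' @param oximetry Long-format oximetry data.frame.
#' @export
write_oximetry_csv <- function(oximetry, path) {
  out <- oximetry[OXIMETRY_COLUMNS]
  out$o2_flag <- as.integer(out$o2_flag)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write the one-row-per-patient table CSV
#'
#' Requires a `patient_id` column; every other column is typed by content
#' (numeric where all non-empty values parse as numbers). Missing values
#' are empty fields.
#'
#' @param path File path.
#' @param required Additional required column names.
#' @return Data.frame.
#' @export
read_patient_csv <- function(path, required = character(0)) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  check_required_columns(df, c("patient_id", required), path)
  for (col in setdiff(names(df), "patient_id")) {
    x <- df[[col]]
    x[x == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(x))
    if (all(is.na(parsed) == is.na(x))) df[[col]] <- parsed else df[[col]] <- x
  }
  df
}

#' @rdname read_patient_csv
#' @param patients Patient data.frame.
#' @export
write_patient_csv <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE, na = "")
  invisible(path)
}

## ---- Orchestration ---------------------------------------------------

#' Pipeline run configuration
#'
#' @param out_dir Output directory for intermediates and the run report.
#' @param sim A [sim_config()] (used when no input CSVs are given).
#' @param oximetry_csv,patients_csv Optional existing inputs; when set the
#'   simulate stage is skipped.
#' @param window,max_minutes,artifact_floor Oximetry metric parameters.
#' @param o2_mode Oxygen quartile mode (see [assign_exposures()]).
#' @param selection_threshold Change-in-estimate threshold.
#' @param caliper Matching caliper (`NULL` = none).
#' @param procedure_floor Rare-procedure exclusion floor.
#' @param stages Character vector of stages to run, in dependency order.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("pacudesat_run_"),
                            sim = sim_config(),
                            oximetry_csv = NULL, patients_csv = NULL,
                            window = 5, max_minutes = 120,
                            artifact_floor = 60, o2_mode = "fraction",
                            selection_threshold = 0.10, caliper = NULL,
                            procedure_floor = 50,
                            stages = c("simulate", "metrics", "thresholds",
                                       "univariate", "fit", "match")) {
  structure(list(out_dir = out_dir, sim = sim,
                 oximetry_csv = oximetry_csv, patients_csv = patients_csv,
                 window = window, max_minutes = max_minutes,
                 artifact_floor = artifact_floor, o2_mode = o2_mode,
                 selection_threshold = selection_threshold,
                 caliper = caliper, procedure_floor = procedure_floor,
                 stages = stages),
            class = "pipeline_config")
}

pipeline_log <- function(stage, msg, verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

## Binary covariates whose 2x2 with the response has every cell >= min_cell
## (zero cells make ML logistic estimates diverge); non-binary covariates
## pass through when they vary.
estimable_covariates <- function(data, response, covariates, min_cell = 2) {
  keep <- vapply(covariates, function(v) {
    x <- data[[v]]
    if (is.null(x)) return(FALSE)
    ok <- !is.na(x) & !is.na(data[[response]])
    x <- x[ok]
    y <- data[[response]][ok]
    if (length(unique(x)) < 2) return(FALSE)
    if (is.numeric(x) && all(x %in% c(0, 1))) {
      all(table(factor(x, levels = c(0, 1)),
                factor(y, levels = c(0, 1))) >= min_cell)
    } else TRUE
  }, logical(1))
  covariates[keep]
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load inputs),
#' stream metrics, population thresholds and exposures, univariate
#' statistics, change-in-estimate modeling with interaction/stratification,
#' and propensity-matched secondary outcomes — writing each intermediate
#' as CSV under `config$out_dir` plus a JSON run report. Identical
#' config and seed reproduce identical outputs; a failing stage is
#' isolated and recorded in the report with its error message.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to standard error.
#' @return The run report (list), invisibly also written to
#'   `report.json`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config[setdiff(names(config), "sim")],
                 sim_seed = config$sim$seed,
                 package_version = as.character(
                   utils::packageVersion("pacudesat")),
                 stages = list(), warnings = character(0))
  run_stage <- function(name, expr) {
    if (!name %in% config$stages && name != "load") return(NULL)
    pipeline_log(name, "starting", verbose)
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "error",
                                     message = conditionMessage(res))
      pipeline_log(name, paste("FAILED:", conditionMessage(res)), verbose)
      NULL
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res$summary)
      res$value
    }
  }

  # -- inputs ------------------------------------------------------------
  if (!is.null(config$oximetry_csv)) {
    oximetry <- read_oximetry_csv(config$oximetry_csv)
    patients <- read_patient_csv(config$patients_csv)
    report$stages$simulate <- list(status = "skipped (inputs supplied)")
  } else {
    sim_out <- run_stage("simulate", {
      cohort <- generate_cohort(config$sim)
      write_oximetry_csv(cohort$oximetry,
                         file.path(config$out_dir, "oximetry.csv"))
      write_patient_csv(cohort$patients,
                        file.path(config$out_dir, "patients.csv"))
      write_truth_json(cohort$truth,
                       file.path(config$out_dir, "truth.json"))
      list(value = cohort,
           summary = list(n_patients = nrow(cohort$patients),
                          n_oximetry_rows = nrow(cohort$oximetry)))
    })
    if (is.null(sim_out)) stop("simulation stage failed; cannot continue")
    oximetry <- sim_out$oximetry
    patients <- sim_out$patients
  }

  # -- metrics + thresholds + exposures -----------------------------------
  phen <- run_stage("thresholds", {
    durations <- stats::setNames(patients$pacu_duration_min,
                                 patients$patient_id)
    ph <- derive_cohort_phenotypes(oximetry, records = patients,
                                   window = config$window,
                                   max_minutes = config$max_minutes,
                                   artifact_floor = config$artifact_floor,
                                   pacu_durations = durations,
                                   o2_mode = config$o2_mode)
    utils::write.csv(ph$measures,
                     file.path(config$out_dir, "measures.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(ph$exposures,
                     file.path(config$out_dir, "exposures.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(unclass(ph$thresholds),
                         file.path(config$out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    list(value = ph,
         summary = list(median_cut = ph$thresholds$median_cut,
                        duration_cut = ph$thresholds$duration_cut,
                        nadir_cut = ph$thresholds$nadir_cut))
  })
  if (is.null(phen)) {
    report_path <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    return(invisible(report))
  }
  analysis <- merge(phen$exposures, patients, by = "patient_id",
                    sort = FALSE)

  # -- univariate ---------------------------------------------------------
  run_stage("univariate", {
    covs <- intersect(names(config$sim$covariate_prevalences),
                      names(analysis))
    vars <- c("nadir_low", "median_low", "duration_high", "o2_quartile",
              covs, "high_risk_surgery")
    tab <- univariate_table(analysis, intersect(vars, names(analysis)))
    audit <- missingness_audit(analysis,
                               variables = intersect(vars, names(analysis)))
    utils::write.csv(tab, file.path(config$out_dir, "univariate.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(audit, file.path(config$out_dir, "missingness.csv"),
                     row.names = FALSE, na = "")
    list(value = tab,
         summary = list(n_variables = length(unique(tab$variable)),
                        n_flagged_missing = sum(audit$flagged)))
  })

  # -- modeling -----------------------------------------------------------
  run_stage("fit", {
    covs <- intersect(names(config$sim$covariate_prevalences),
                      names(analysis))
    complete <- analysis[!is.na(analysis$nadir_low) &
                           !is.na(analysis$o2_quartile), , drop = FALSE]
    covs <- estimable_covariates(complete, "early_prc", covs)
    model <- change_in_estimate_selection(
      "early_prc", exposure = c("nadir_low", "o2_quartile"),
      candidates = covs, data = complete,
      threshold = config$selection_threshold)
    utils::write.csv(model$coef_table,
                     file.path(config$out_dir, "model_coefficients.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(model$ledger,
                     file.path(config$out_dir, "selection_ledger.csv"),
                     row.names = FALSE, na = "")
    inter <- interaction_analysis("early_prc", "nadir_low",
                                  "high_risk_surgery", data = complete)
    strat <- NULL
    if (isTRUE(inter$stratify)) {
      strat <- stratified_models("early_prc",
                                 exposure = c("nadir_low", "o2_quartile"),
                                 candidates = covs, data = complete,
                                 stratifier = "high_risk_surgery",
                                 threshold = config$selection_threshold)
    }
    list(value = list(model = model, interaction = inter,
                      stratified = strat),
         summary = list(
           n_model = nrow(complete),
           exposure_aor = model$coef_table$aor[
             model$coef_table$term == "nadir_low"],
           c_statistic = model$diagnostics$c_statistic,
           interaction_p = inter$interaction_p,
           stratified = isTRUE(inter$stratify)))
  })

  # -- matching -----------------------------------------------------------
  run_stage("match", {
    dat <- analysis[!is.na(analysis$o2_quartile), , drop = FALSE]
    dat$o2_above_q1 <- as.integer(dat$o2_quartile > 1)
    filt <- exclude_rare_procedures(dat, floor = config$procedure_floor)
    dat <- filt$records
    covs <- intersect(c(names(config$sim$covariate_prevalences),
                        "age", "weight_kg", "anesthesia_duration_min",
                        "body_region"), names(dat))
    covs <- estimable_covariates(dat, "o2_above_q1", covs)
    ps <- fit_propensity("o2_above_q1", covs, dat)
    matched <- nearest_neighbor_match(ps$scores, dat$o2_above_q1,
                                      ids = dat$patient_id,
                                      caliper = config$caliper)
    bal <- balance_table(matched, dat,
                         setdiff(covs, "body_region"), "o2_above_q1")
    outc <- matched_outcomes(matched, dat, "o2_above_q1",
                             o2_quartile = "o2_quartile")
    utils::write.csv(matched$pairs,
                     file.path(config$out_dir, "matched_pairs.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(bal, file.path(config$out_dir, "balance.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(outc$continuous,
                     file.path(config$out_dir, "matched_continuous.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(outc$binary,
                     file.path(config$out_dir, "matched_binary.csv"),
                     row.names = FALSE, na = "")
    list(value = list(matched = matched, balance = bal, outcomes = outc,
                      excluded = filt$excluded),
         summary = list(n_pairs = nrow(matched$pairs),
                        n_excluded_categories = nrow(filt$excluded),
                        max_post_smd = max(abs(bal$post_smd))))
  })

  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  pipeline_log("report", paste("written to", report_path), verbose)
  invisible(report)
}
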