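#' Population centile by linear interpolation of order statistics
#'
#' The quantile convention used throughout threshold derivation: linear
#' interpolation between order statistics at position `1 + p * (n - 1)`
#' (the common "type 7" rule).
#'
#' @param values Numeric values; `NA`s are dropped.
#' @param p Proportion in [0, 1].
#' @return Scalar quantile.
#' @export
centile <- function(values, p) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("centile of an empty value set is undefined")
  if (!is.numeric(p) || any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

#' Devine ideal body weight
#'
#' 50 kg (male) or 45.5 kg (female) plus 2.3 kg per inch of height over
#' 60 inches; used to normalize drug doses.
#'
#' @param height_cm Height in centimetres, in [100, 250].
#' @param sex `"male"` or `"female"` (vectorized).
#' @return Ideal body weight in kg.
#' @export
ideal_body_weight <- function(height_cm, sex) {
  if (any(is.na(height_cm)) || any(height_cm < 100 | height_cm > 250)) {
    stop("height must lie in [100, 250] cm")
  }
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  base <- ifelse(sex == "male", 50, 45.5)
  inches <- height_cm / 2.54
  base + 2.3 * pmax(0, inches - 60)
}

#' Normalize a neuromuscular blocker dose
#'
#' Total intraoperative dose per kilogram of ideal body weight per hour of
#' anesthesia. High-dose use is flagged downstream at the agent-specific
#' 75th population centile ("equal to or greater than" the cut).
#'
#' @param total_dose_mg Total dose in mg.
#' @param ibw_kg Ideal body weight in kg (> 0).
#' @param anesthesia_duration_min Anesthesia time in minutes (> 0).
#' @return Dose in mg.kg^-1.hr^-1; `NA` with attribute `reason` when a
#'   denominator is nonpositive.
#' @export
normalize_nmba_dose <- function(total_dose_mg, ibw_kg,
                                anesthesia_duration_min) {
  out <- total_dose_mg / ibw_kg / (anesthesia_duration_min / 60)
  bad <- is.na(ibw_kg) | is.na(anesthesia_duration_min) |
    ibw_kg <= 0 | anesthesia_duration_min <= 0
  if (any(bad)) {
    out[bad] <- NA_real_
    attr(out, "reason") <- "nonpositive_denominator"
  }
  out
}

#' Default opioid to morphine-equivalent conversion factors
#'
#' Milligram-equivalents of morphine per milligram of agent. These are
#' conventional equianalgesic assumptions shipped as an editable default.
#'
#' @return Named numeric vector.
#' @export
default_opioid_conversions <- function() {
  c(morphine = 1, hydromorphone = 6.67, fentanyl = 100)
}

#' Intraoperative morphine equivalents, dose-normalized
#'
#' Sums agent doses times their morphine-equivalent factors, then
#' normalizes per ideal body weight and anesthesia hour.
#'
#' @param administrations Data.frame with columns `agent` and `dose_mg`.
#' @param ibw_kg Ideal body weight (kg).
#' @param anesthesia_duration_min Anesthesia time (minutes).
#' @param conversion_table Named factors (see
#'   [default_opioid_conversions()]).
#' @return Normalized morphine equivalents in mg.kg^-1.hr^-1.
#' @export
morphine_equivalents <- function(administrations, ibw_kg,
                                 anesthesia_duration_min,
                                 conversion_table =
                                   default_opioid_conversions()) {
  if (nrow(administrations) == 0) return(0)
  unknown <- setdiff(unique(administrations$agent), names(conversion_table))
  if (length(unknown) > 0) {
    stop("no conversion factor for agent(s): ",
         paste(unknown, collapse = ", "))
  }
  total <- sum(administrations$dose_mg *
                 conversion_table[administrations$agent])
  as.numeric(normalize_nmba_dose(total, ibw_kg, anesthesia_duration_min))
}

#' Surgical complexity score from body-region indicators
#'
#' Fits a logistic regression of the study outcome on procedure body-region
#' indicators; the per-patient fitted linear predictor is the continuous
#' complexity score, dichotomized as higher risk at its 75th centile
#' (`>=` rule).
#'
#' @param records Data.frame with columns `body_region` and the outcome.
#' @param outcome Outcome column name (default `"early_prc"`).
#' @return List with `score` (per patient), `high_risk` (0/1),
#'   `cut` (75th-centile score) and `degenerate` flag.
#' @export
surgical_complexity_score <- function(records, outcome = "early_prc") {
  region <- factor(records$body_region)
  y <- records[[outcome]]
  if (nlevels(region) < 2) {
    warning("single body region: complexity score is degenerate (constant)")
    score <- rep(0, nrow(records))
    return(list(score = score, high_risk = rep(0L, nrow(records)),
                cut = 0, degenerate = TRUE))
  }
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("both outcome classes are required to fit the complexity score")
  }
  fit <- stats::glm(y ~ region, family = stats::binomial())
  score <- as.numeric(stats::predict(fit, type = "link"))
  cut <- centile(score, 0.75)
  list(score = score, high_risk = as.integer(score >= cut), cut = cut,
       degenerate = FALSE)
}

#' Derive population thresholds for the desaturation phenotypes
#'
#' Computes the cohort-level centile cutoffs that turn the continuous
#' desaturation measures into phenotypes: the 10th centile of per-patient
#' median SpO2 values, the 90th centile of desaturation duration, the 10th
#' centile of nadirs, oxygen-fraction quartile bounds, and the 75th-centile
#' cuts for normalized drug doses and durations where present. Every cut is
#' computed over non-missing values only and is reported with the n used.
#'
#' @param measures Per-patient measures from [compute_desat_measures()]
#'   (the `minutes_below_level` column must be populated at the median-cut
#'   level before the duration cut can be derived; see
#'   [derive_cohort_phenotypes()] for the orchestrated two-pass flow).
#' @param records Optional patient table supplying `nmba_rate` (with
#'   `nmba_agent`), `morphine_eq_rate`, `mac_minutes`,
#'   `anesthesia_duration_min` and/or `complexity_score` columns for the
#'   75th-centile cuts.
#' @return Object of class `population_thresholds`.
#' @export
derive_thresholds <- function(measures, records = NULL) {
  n_of <- function(x) sum(!is.na(x))
  cut_or_na <- function(x, p) if (n_of(x) > 0) centile(x, p) else NA_real_
  thr <- list(
    median_cut = cut_or_na(measures$median_spo2, 0.10),
    duration_cut = cut_or_na(measures$minutes_below_level, 0.90),
    nadir_cut = cut_or_na(measures$nadir_spo2, 0.10),
    o2_quartile_bounds = if (n_of(measures$o2_fraction) > 0)
      c(centile(measures$o2_fraction, 0.25),
        centile(measures$o2_fraction, 0.50),
        centile(measures$o2_fraction, 0.75)) else rep(NA_real_, 3),
    n_used = c(median = n_of(measures$median_spo2),
               duration = n_of(measures$minutes_below_level),
               nadir = n_of(measures$nadir_spo2),
               o2 = n_of(measures$o2_fraction))
  )
  if (!is.null(records)) {
    if (!is.null(records$nmba_rate) && !is.null(records$nmba_agent)) {
      agents <- setdiff(unique(records$nmba_agent), c(NA, "none"))
      thr$nmba_high_dose_cuts <- vapply(agents, function(a) {
        cut_or_na(records$nmba_rate[records$nmba_agent == a], 0.75)
      }, numeric(1))
    }
    if (!is.null(records$morphine_eq_rate)) {
      thr$opioid_dose_cut <- cut_or_na(records$morphine_eq_rate, 0.75)
    }
    if (!is.null(records$mac_minutes)) {
      thr$mac_duration_cut <- cut_or_na(records$mac_minutes, 0.75)
    }
    if (!is.null(records$anesthesia_duration_min)) {
      thr$anesthesia_duration_cut <-
        cut_or_na(records$anesthesia_duration_min, 0.75)
    }
    if (!is.null(records$complexity_score)) {
      thr$complexity_cut <- cut_or_na(records$complexity_score, 0.75)
    }
  }
  structure(thr, class = "population_thresholds")
}

#' @export
print.population_thresholds <- function(x, ...) {
  cat("<population_thresholds>\n")
  cat(sprintf("  median SpO2 cut (10th centile): %.2f%% (n=%d)\n",
              x$median_cut, x$n_used[["median"]]))
  cat(sprintf("  duration cut (90th centile):    %.2f min/hr (n=%d)\n",
              x$duration_cut, x$n_used[["duration"]]))
  cat(sprintf("  nadir cut (10th centile):       %.2f%% (n=%d)\n",
              x$nadir_cut, x$n_used[["nadir"]]))
  cat(sprintf("  O2 fraction quartile bounds:    %s\n",
              paste(sprintf("%.3f", x$o2_quartile_bounds), collapse = ", ")))
  invisible(x)
}

#' Assign per-patient exposure phenotypes from thresholds
#'
#' Applies the boundary conventions of the threshold definitions: strict
#' `<` for the nadir and median cuts, `>=` for the duration cut and all
#' 75th-centile flags, and quartile assignment of the oxygen fraction
#' (`o2_quartile` in 1..4). When the stay is the standard 120-minute
#' censored stay, minute-bin labels (<30, 31-60, 61-90, >90 min) are also
#' reported. Missing measures yield missing exposures.
#'
#' @param measures Per-patient measures (with `minutes_below_level`
#'   populated at the median-cut level).
#' @param thresholds A [derive_thresholds()] result.
#' @param records Optional patient table (for pass-through columns).
#' @param o2_mode `"fraction"` (quartiles of the cohort's oxygen fraction)
#'   or `"minutes"` (fixed <30/31-60/61-90/>90-minute bins at a 120-minute
#'   stay).
#' @return Data.frame of exposures, one row per patient.
#' @export
assign_exposures <- function(measures, thresholds, records = NULL,
                             o2_mode = c("fraction", "minutes")) {
  o2_mode <- match.arg(o2_mode)
  o2_quartile <- if (o2_mode == "fraction") {
    if (anyNA(thresholds$o2_quartile_bounds)) {
      rep(NA_integer_, nrow(measures))
    } else {
      as.integer(findInterval(measures$o2_fraction,
                              thresholds$o2_quartile_bounds) + 1L)
    }
  } else {
    as.integer(findInterval(measures$o2_duration_min, c(30, 60, 90),
                            left.open = TRUE) + 1L)
  }
  out <- data.frame(
    patient_id = measures$patient_id,
    nadir_low = as.integer(measures$nadir_spo2 < thresholds$nadir_cut),
    median_low = as.integer(measures$median_spo2 < thresholds$median_cut),
    duration_high = as.integer(measures$minutes_below_level >=
                                 thresholds$duration_cut),
    o2_quartile = o2_quartile,
    stringsAsFactors = FALSE
  )
  if (is.na(thresholds$nadir_cut)) out$nadir_low <- NA_integer_
  if (is.na(thresholds$median_cut)) out$median_low <- NA_integer_
  if (is.na(thresholds$duration_cut)) out$duration_high <- NA_integer_
  if (!is.null(records)) {
    if (!is.null(records$nmba_rate) && !is.null(records$nmba_agent) &&
        !is.null(thresholds$nmba_high_dose_cuts)) {
      cuts <- thresholds$nmba_high_dose_cuts[records$nmba_agent]
      out$high_dose_nmba <- as.integer(!is.na(cuts) &
                                         records$nmba_rate >= cuts)
    }
    if (!is.null(records$morphine_eq_rate) &&
        !is.null(thresholds$opioid_dose_cut)) {
      out$opioid_high <- as.integer(records$morphine_eq_rate >=
                                      thresholds$opioid_dose_cut)
    }
    if (!is.null(records$mac_minutes) &&
        !is.null(thresholds$mac_duration_cut)) {
      out$mac_high <- as.integer(records$mac_minutes >=
                                   thresholds$mac_duration_cut)
    }
    if (!is.null(records$anesthesia_duration_min) &&
        !is.null(thresholds$anesthesia_duration_cut)) {
      out$anesthesia_long <- as.integer(records$anesthesia_duration_min >=
                                          thresholds$anesthesia_duration_cut)
    }
    if (!is.null(records$complexity_score) &&
        !is.null(thresholds$complexity_cut)) {
      out$high_risk_surgery <- as.integer(records$complexity_score >=
                                            thresholds$complexity_cut)
    }
  }
  out
}

#' Two-pass phenotype derivation for a cohort of streams
#'
#' Orchestrates the order-sensitive part of threshold derivation: the
#' duration measure counts minutes below the *population* median cutoff, so
#' medians must be summarized across the cohort before any duration can be
#' computed. Pass one computes median/nadir/oxygen per patient and the 10th
#' centile of medians; pass two computes minutes-below-level at that cut
#' and the 90th-centile duration threshold.
#'
#' @param streams Stream list or long-format oximetry data.frame.
#' @param records Optional patient table forwarded to
#'   [derive_thresholds()].
#' @inheritParams compute_desat_measures
#' @return List with `measures`, `thresholds` and `exposures`.
#' @export
derive_cohort_phenotypes <- function(streams, records = NULL, window = 5,
                                     max_minutes = 120, artifact_floor = 60,
                                     pacu_durations = NULL,
                                     o2_mode = "fraction") {
  if (is.data.frame(streams)) streams <- as_stream_list(streams,
                                                        pacu_durations)
  measures <- compute_desat_measures(streams, level = NA, window = window,
                                     max_minutes = max_minutes,
                                     artifact_floor = artifact_floor)
  median_cut <- if (any(!is.na(measures$median_spo2)))
    centile(measures$median_spo2, 0.10) else NA_real_
  if (!is.na(median_cut)) {
    dur <- vapply(streams, function(s) {
      as.numeric(minutes_below_level(s, median_cut,
                                     max_minutes = max_minutes,
                                     artifact_floor = artifact_floor))
    }, numeric(1))
    measures$minutes_below_level <- unname(dur)
    measures$duration_reason[!is.na(dur)] <- NA_character_
  }
  thresholds <- derive_thresholds(measures, records)
  exposures <- assign_exposures(measures, thresholds, records,
                                o2_mode = o2_mode)
  list(measures = measures, thresholds = thresholds, exposures = exposures)
}
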