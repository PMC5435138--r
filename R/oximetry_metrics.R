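#' Censor and clean an oximetry stream
#'
#' Truncates the continuous record to the first `max_minutes` of the PACU
#' stay (half-open window `[0, max_minutes)`) and marks physiologically
#' implausible saturations below `artifact_floor` as missing. Pulse oximetry
#' is not validated below 60% and sensor-dislodgement artifacts concentrate
#' there, so such values are treated as artifact, not signal. Manual entries
#' are retained regardless of minute as long as they fall within the stay.
#'
#' @param stream An [oximetry_stream()].
#' @param max_minutes Censoring horizon in minutes (default 120).
#' @param artifact_floor Lowest saturation accepted as real (default 60%).
#' @return A cleaned `oximetry_stream`; cleaning is total (never errors).
#'   The samples gain a `reason` column (`NA` or `"artifact"`).
#' @export
censor_and_clean <- function(stream, max_minutes = 120, artifact_floor = 60) {
  s <- stream$samples
  cont <- s$source == "continuous"
  keep <- (!cont & s$minute < stream$pacu_duration_min) |
    (cont & s$minute >= 0L & s$minute < max_minutes)
  s <- s[keep, , drop = FALSE]
  s$reason <- NA_character_
  artifact <- !is.na(s$spo2) & s$spo2 < artifact_floor
  s$spo2[artifact] <- NA_real_
  s$reason[artifact] <- "artifact"
  rownames(s) <- NULL
  out <- stream
  out$samples <- s
  out
}

## Continuous spo2 laid out as a by-minute vector over [0, span); minutes
## with no sample or an artifact come back NA.
spo2_by_minute <- function(stream, span, artifact_floor = 60) {
  s <- stream$samples
  cont <- s$source == "continuous" & s$minute >= 0L & s$minute < span
  v <- rep(NA_real_, span)
  sp <- s$spo2[cont]
  sp[!is.na(sp) & sp < artifact_floor] <- NA_real_
  v[s$minute[cont] + 1L] <- sp
  v
}

#' Sliding-window medians of a continuous SpO2 record
#'
#' Computes the median SpO2 for every 5-minute window advanced one minute at
#' a time across the censored monitoring span. A window yields a median only
#' when at least `min_nonmissing` of its minutes carry a valid sample;
#' sparser windows are dropped so that one stray sample cannot masquerade as
#' a central-tendency estimate.
#'
#' @param stream An [oximetry_stream()] (cleaning rules are applied
#'   internally, so a raw stream is acceptable).
#' @param window Window width in minutes (default 5).
#' @param step Advance between window positions in minutes (default 1).
#' @param max_minutes Censoring horizon (default 120).
#' @param artifact_floor Artifact exclusion floor (default 60).
#' @param min_nonmissing Minimum valid samples a window needs; defaults to
#'   `ceiling(window / 2)`.
#' @return Numeric vector of window medians (possibly length zero), with the
#'   0-based start minute of each retained window in attribute `"start"`.
#' @export
sliding_window_medians <- function(stream, window = 5, step = 1,
                                   max_minutes = 120, artifact_floor = 60,
                                   min_nonmissing = ceiling(window / 2)) {
  cont_min <- stream$samples$minute[stream$samples$source == "continuous"]
  span <- if (length(cont_min) == 0) 0L else min(max_minutes, max(cont_min) + 1L)
  if (span < window) {
    out <- numeric(0)
    attr(out, "start") <- integer(0)
    return(out)
  }
  v <- spo2_by_minute(stream, span, artifact_floor)
  starts <- seq.int(0L, span - window, by = step)
  med <- vapply(starts, function(t0) {
    w <- v[(t0 + 1L):(t0 + window)]
    w <- w[!is.na(w)]
    if (length(w) >= min_nonmissing) stats::median(w) else NA_real_
  }, numeric(1))
  ok <- !is.na(med)
  out <- med[ok]
  attr(out, "start") <- starts[ok]
  out
}

#' Median PACU SpO2 (median of sliding-window medians)
#'
#' The per-patient central-tendency measure: the median over all retained
#' 5-minute sliding-window medians within the censored span. Even-length
#' medians use the mean of the two central order statistics.
#'
#' @inheritParams sliding_window_medians
#' @return Scalar percent, or `NA` with attribute
#'   `reason = "insufficient_data"` when no window is computable.
#' @export
median_spo2 <- function(stream, window = 5, max_minutes = 120,
                        artifact_floor = 60,
                        min_nonmissing = ceiling(window / 2)) {
  wm <- sliding_window_medians(stream, window = window,
                               max_minutes = max_minutes,
                               artifact_floor = artifact_floor,
                               min_nonmissing = min_nonmissing)
  if (length(wm) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "insufficient_data"
    return(out)
  }
  stats::median(as.numeric(wm))
}

#' Desaturation duration below a saturation level
#'
#' Cumulative time spent below `level`, expressed as minutes per hour of
#' monitored PACU time within the censored span: `60 * (# valid continuous
#' minutes with SpO2 < level) / (# valid continuous minutes)`.
#'
#' @inheritParams sliding_window_medians
#' @param level Saturation level in percent; typically the population median
#'   cutoff (94% in the derivation cohort this measure comes from).
#' @return Minutes per hour in `[0, 60]`, or `NA` with
#'   `reason = "insufficient_data"` when no valid minute exists.
#' @export
minutes_below_level <- function(stream, level, max_minutes = 120,
                                artifact_floor = 60) {
  cont_min <- stream$samples$minute[stream$samples$source == "continuous"]
  span <- if (length(cont_min) == 0) 0L else min(max_minutes, max(cont_min) + 1L)
  v <- if (span > 0) spo2_by_minute(stream, span, artifact_floor) else numeric(0)
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "insufficient_data"
    return(out)
  }
  60 * sum(v < level) / length(v)
}

## Maximal runs of oxygen-off continuous minutes over the full stay;
## returns per-minute run length (0 where oxygen on / minute unobserved).
o2_off_run_lengths <- function(stream) {
  s <- stream$samples
  cont <- s$source == "continuous"
  n <- stream$pacu_duration_min
  off <- rep(FALSE, n)
  idx <- s$minute[cont] + 1L
  off[idx] <- !s$o2_flag[cont]
  r <- rle(off)
  run_len <- rep(r$lengths, r$lengths)
  run_len[!off] <- 0L
  run_len
}

#' Nadir SpO2 over the full PACU stay
#'
#' The lowest valid saturation the patient reached: the minimum over (i) all
#' continuous samples from first recording through PACU discharge (not
#' censored at 120 minutes) and (ii) manual room-air entries charted inside
#' an oxygen-off epoch lasting at least `min_room_air_epoch` minutes. The
#' artifact floor applies to both candidate sets.
#'
#' @inheritParams sliding_window_medians
#' @param min_room_air_epoch Minimum consecutive oxygen-off minutes around a
#'   manual entry for it to qualify (default 5).
#' @param censor At `FALSE` (default) the search runs through PACU
#'   discharge; at `TRUE` the continuous record is censored at
#'   `max_minutes` first.
#' @return Scalar percent, or `NA` with `reason = "insufficient_data"`.
#' @export
nadir_spo2 <- function(stream, artifact_floor = 60, min_room_air_epoch = 5,
                       censor = FALSE, max_minutes = 120) {
  s <- stream$samples
  cont <- s$source == "continuous"
  if (censor) cont <- cont & s$minute < max_minutes
  cand <- s$spo2[cont]
  manual <- which(!cont & s$source == "manual_room_air" &
                    s$minute < stream$pacu_duration_min)
  if (length(manual) > 0) {
    run_len <- o2_off_run_lengths(stream)
    ok <- vapply(manual, function(i) {
      m <- s$minute[i] + 1L
      m >= 1L && m <= length(run_len) && run_len[m] >= min_room_air_epoch
    }, logical(1))
    cand <- c(cand, s$spo2[manual[ok]])
  }
  cand <- cand[!is.na(cand) & cand >= artifact_floor]
  if (length(cand) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "insufficient_data"
    return(out)
  }
  min(cand)
}

#' Supplemental oxygen exposure over the PACU stay
#'
#' Counts minutes with documented oxygen therapy over the full stay (not
#' censored at 120 minutes) and expresses them as a fraction of the stay.
#'
#' @param stream An [oximetry_stream()] with `pacu_duration_min > 0`.
#' @return List with `o2_duration_min` and `o2_fraction`.
#' @export
oxygen_exposure <- function(stream) {
  if (stream$pacu_duration_min <= 0) {
    stop("oxygen_exposure needs a positive PACU stay length")
  }
  s <- stream$samples
  cont <- s$source == "continuous"
  dur <- sum(s$o2_flag[cont], na.rm = TRUE)
  list(o2_duration_min = as.integer(dur),
       o2_fraction = dur / stream$pacu_duration_min)
}

#' Per-patient desaturation measures
#'
#' Computes the four stream-level desaturation measures for one patient:
#' median-of-sliding-medians SpO2, minutes per hour below `level` (when a
#' level is supplied), nadir SpO2, and oxygen-therapy duration/fraction.
#' Central tendency and duration use the 120-minute censored span; nadir and
#' oxygen exposure use the full stay, matching their definitions.
#'
#' @inheritParams nadir_spo2
#' @param level Saturation level for the duration measure, or `NA` to defer
#'   it (the level is a population centile, so a first pass typically runs
#'   without it).
#' @param window Sliding-window width in minutes.
#' @return One-row data.frame with the measures, `monitored_minutes`, and a
#'   reason code per measure (`NA` when the measure is present).
#' @export
desat_measures <- function(stream, level = NA, window = 5, max_minutes = 120,
                           artifact_floor = 60, min_room_air_epoch = 5,
                           censor = FALSE) {
  med <- median_spo2(stream, window = window, max_minutes = max_minutes,
                     artifact_floor = artifact_floor)
  dur <- if (is.na(level)) {
    structure(NA_real_, reason = "no_level")
  } else {
    minutes_below_level(stream, level, max_minutes = max_minutes,
                        artifact_floor = artifact_floor)
  }
  nad <- nadir_spo2(stream, artifact_floor = artifact_floor,
                    min_room_air_epoch = min_room_air_epoch,
                    censor = censor, max_minutes = max_minutes)
  o2 <- oxygen_exposure(stream)
  cont_min <- stream$samples$minute[stream$samples$source == "continuous"]
  span <- if (length(cont_min) == 0) 0L else min(max_minutes, max(cont_min) + 1L)
  mon <- if (span > 0) {
    sum(!is.na(spo2_by_minute(stream, span, artifact_floor)))
  } else 0L
  reason_of <- function(x) {
    r <- attr(x, "reason")
    if (is.null(r)) NA_character_ else r
  }
  data.frame(
    patient_id = stream$patient_id,
    median_spo2 = as.numeric(med),
    minutes_below_level = as.numeric(dur),
    nadir_spo2 = as.numeric(nad),
    o2_duration_min = o2$o2_duration_min,
    o2_fraction = o2$o2_fraction,
    monitored_minutes = as.integer(mon),
    median_reason = reason_of(med),
    duration_reason = reason_of(dur),
    nadir_reason = reason_of(nad),
    stringsAsFactors = FALSE
  )
}

#' Desaturation measures for a cohort of streams
#'
#' @param streams A list of [oximetry_stream()] objects or a long-format
#'   oximetry data.frame (see [as_stream_list()]).
#' @inheritParams desat_measures
#' @param pacu_durations Optional named stay lengths, used when `streams` is
#'   a data.frame.
#' @return Data.frame with one row per patient.
#' @export
compute_desat_measures <- function(streams, level = NA, window = 5,
                                   max_minutes = 120, artifact_floor = 60,
                                   min_room_air_epoch = 5, censor = FALSE,
                                   pacu_durations = NULL) {
  if (is.data.frame(streams)) {
    streams <- as_stream_list(streams, pacu_durations)
  }
  rows <- lapply(streams, desat_measures, level = level, window = window,
                 max_minutes = max_minutes, artifact_floor = artifact_floor,
                 min_room_air_epoch = min_room_air_epoch, censor = censor)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
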