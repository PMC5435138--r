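#' Construct a PACU oximetry stream
#'
#' An oximetry stream holds one patient's per-minute pulse-oximetry record
#' during the post-anesthesia care unit (PACU) stay: continuous monitor
#' samples (at most one per minute) plus optional manual room-air entries
#' charted by the PACU nurse.
#'
#' @param patient_id Scalar identifier.
#' @param samples A data.frame with columns `minute` (integer minutes from
#'   PACU admission, 0-based), `spo2` (percent saturation, may be `NA`),
#'   `o2_flag` (logical, documented supplemental oxygen), and `source`
#'   (`"continuous"` or `"manual_room_air"`).
#' @param pacu_duration_min Total PACU stay in minutes; must be at least the
#'   last continuous minute index plus one.
#'
#' @return An object of class `oximetry_stream`.
#' @export
oximetry_stream <- function(patient_id, samples, pacu_duration_min = NULL) {
  required <- c("minute", "spo2", "o2_flag", "source")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("samples is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  samples <- samples[required]
  samples$minute <- as.integer(samples$minute)
  samples$spo2 <- as.numeric(samples$spo2)
  samples$o2_flag <- as.logical(samples$o2_flag)
  samples$source <- as.character(samples$source)
  bad_source <- setdiff(unique(samples$source), c("continuous", "manual_room_air"))
  if (length(bad_source) > 0) {
    stop("unknown sample source(s): ", paste(bad_source, collapse = ", "))
  }
  cont <- samples$source == "continuous"
  if (anyDuplicated(samples$minute[cont])) {
    stop("more than one continuous sample in a single minute")
  }
  if (any(samples$o2_flag[!cont], na.rm = TRUE)) {
    stop("manual room-air entries must carry o2_flag = FALSE")
  }
  samples <- samples[order(samples$minute, samples$source != "continuous"), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(pacu_duration_min)) {
    pacu_duration_min <- if (any(cont)) max(samples$minute[cont]) + 1L else 0L
  }
  if (any(cont) && pacu_duration_min < max(samples$minute[cont]) + 1L) {
    stop("pacu_duration_min is shorter than the last continuous minute")
  }
  structure(
    list(patient_id = patient_id,
         samples = samples,
         pacu_duration_min = as.integer(pacu_duration_min)),
    class = "oximetry_stream"
  )
}

#' @export
print.oximetry_stream <- function(x, ...) {
  cont <- x$samples$source == "continuous"
  cat("<oximetry_stream> patient", x$patient_id, "-",
      sum(cont), "continuous minutes,",
      sum(!cont), "manual entries,",
      "PACU stay", x$pacu_duration_min, "min\n")
  invisible(x)
}

#' Split a long-format oximetry table into streams
#'
#' @param oximetry Long-format data.frame with columns `patient_id`,
#'   `minute`, `spo2`, `o2_flag`, `source`.
#' @param pacu_durations Optional named vector of PACU stay lengths in
#'   minutes, names matching patient ids; when absent the stay is inferred
#'   as last continuous minute + 1.
#' @return Named list of [oximetry_stream()] objects.
#' @export
as_stream_list <- function(oximetry, pacu_durations = NULL) {
  stopifnot(is.data.frame(oximetry))
  ids <- unique(oximetry$patient_id)
  out <- lapply(ids, function(id) {
    rows <- oximetry[oximetry$patient_id == id,
                     c("minute", "spo2", "o2_flag", "source"), drop = FALSE]
    dur <- if (!is.null(pacu_durations)) unname(pacu_durations[[as.character(id)]])
           else NULL
    oximetry_stream(id, rows, dur)
  })
  names(out) <- as.character(ids)
  out
}
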