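# Compact constructor for hand-built continuous streams.
make_stream <- function(spo2, o2 = rep(FALSE, length(spo2)),
                        stay = length(spo2), id = "T1", manual = NULL) {
  df <- data.frame(minute = seq_along(spo2) - 1L, spo2 = spo2,
                   o2_flag = o2, source = "continuous",
                   stringsAsFactors = FALSE)
  if (!is.null(manual)) df <- rbind(df, manual)
  oximetry_stream(id, df, stay)
}

manual_entry <- function(minute, spo2) {
  data.frame(minute = minute, spo2 = spo2, o2_flag = FALSE,
             source = "manual_room_air", stringsAsFactors = FALSE)
}
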