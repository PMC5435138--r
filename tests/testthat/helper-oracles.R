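# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from its definition with naive loops, sharing no
# code path with the package implementation.

# Naive recomputation of all four desaturation measures for one stream.
oracle_measures <- function(stream, level = 94, max_minutes = 120,
                            floor = 60, window = 5) {
  s <- stream$samples
  cont <- s[s$source == "continuous", , drop = FALSE]
  valid <- function(x) !is.na(x) & x >= floor
  cens <- cont[cont$minute < max_minutes & cont$minute >= 0, , drop = FALSE]
  # the censored span runs to the earlier of the censor horizon and the end
  # of continuous monitoring (even if the last in-span minutes lack samples)
  span <- if (nrow(cont) > 0) min(max_minutes, max(cont$minute) + 1) else 0
  by_min <- rep(NA_real_, max(span, 1))
  if (nrow(cens) > 0) by_min[cens$minute + 1] <- ifelse(valid(cens$spo2),
                                                        cens$spo2, NA)
  meds <- numeric(0)
  if (span >= window) {
    for (t in 0:(span - window)) {
      vals <- by_min[(t + 1):(t + window)]
      vals <- vals[!is.na(vals)]
      if (length(vals) >= ceiling(window / 2)) {
        meds <- c(meds, stats::median(vals))
      }
    }
  }
  med <- if (length(meds) > 0) stats::median(meds) else NA_real_
  mon <- sum(valid(cens$spo2))
  dur <- if (mon > 0) {
    60 * sum(valid(cens$spo2) & cens$spo2 < level) / mon
  } else NA_real_
  cand <- cont$spo2[valid(cont$spo2)]
  man <- s[s$source == "manual_room_air" &
             s$minute < stream$pacu_duration_min, , drop = FALSE]
  if (nrow(man) > 0) {
    off <- rep(FALSE, stream$pacu_duration_min)
    off[cont$minute + 1] <- !cont$o2_flag
    for (i in seq_len(nrow(man))) {
      m <- man$minute[i] + 1
      if (m >= 1 && m <= length(off) && off[m] && valid(man$spo2[i])) {
        lo <- m
        while (lo > 1 && off[lo - 1]) lo <- lo - 1
        hi <- m
        while (hi < length(off) && off[hi + 1]) hi <- hi + 1
        if (hi - lo + 1 >= 5) cand <- c(cand, man$spo2[i])
      }
    }
  }
  nad <- if (length(cand) > 0) min(cand) else NA_real_
  o2min <- sum(cont$o2_flag)
  list(median_spo2 = med, minutes_below_level = dur, nadir_spo2 = nad,
       o2_duration_min = o2min,
       o2_fraction = o2min / stream$pacu_duration_min,
       monitored_minutes = mon)
}

# Random messy stream (gaps, artifacts, missing values, manual entries),
# independent of the package generator.
random_messy_stream <- function(seed, max_len = 200) {
  set.seed(seed)
  n <- sample(10:max_len, 1)
  stay <- n + sample(0:30, 1)
  k <- max(6, rbinom(1, n, 0.9))
  minutes <- sort(sample(0:(n - 1), k))
  spo2 <- sample(40:100, k, replace = TRUE)
  spo2[runif(k) < 0.05] <- NA
  o2 <- runif(k) < 0.4
  df <- data.frame(minute = minutes, spo2 = spo2, o2_flag = o2,
                   source = "continuous", stringsAsFactors = FALSE)
  m <- rpois(1, 1.5)
  if (m > 0) {
    df <- rbind(df, data.frame(minute = sample(0:(stay - 1), m),
                               spo2 = sample(55:100, m, replace = TRUE),
                               o2_flag = FALSE, source = "manual_room_air",
                               stringsAsFactors = FALSE))
  }
  oximetry_stream(sprintf("R%05d", seed), df, stay)
}

# All-pairs concordance with half credit for ties.
oracle_concordance <- function(scores, y) {
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  tot <- 0
  for (a in cases) {
    for (b in controls) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  tot / (length(cases) * length(controls))
}

# Exhaustive trace of greedy descending-score 1:1 matching.
oracle_greedy_match <- function(scores, exposed, caliper = NULL) {
  e <- which(as.logical(exposed))
  ctl <- which(!as.logical(exposed))
  used <- rep(FALSE, length(ctl))
  pairs <- list()
  for (i in e[order(scores[e], decreasing = TRUE)]) {
    best <- NA
    best_gap <- Inf
    for (j in seq_along(ctl)) {
      if (used[j]) next
      gap <- abs(scores[i] - scores[ctl[j]])
      if (gap < best_gap) {
        best <- j
        best_gap <- gap
      }
    }
    if (is.na(best)) next
    if (!is.null(caliper) && best_gap > caliper) next
    used[best] <- TRUE
    pairs[[length(pairs) + 1]] <- c(exposed = i, control = ctl[best])
  }
  if (length(pairs) == 0) {
    return(data.frame(exposed = integer(0), control = integer(0)))
  }
  as.data.frame(do.call(rbind, pairs))
}

# Mann-Whitney U as pairwise wins + half ties.
oracle_u_statistic <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + if (a > b) 1 else if (a == b) 0.5 else 0
  u
}

# Type-7 quantile by direct sort-and-interpolate.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- 1 + p * (n - 1)
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
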