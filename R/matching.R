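#' Exclude rare procedure categories
#'
#' Drops patients whose procedure category occurs fewer than `floor` times
#' in the dataset, so that procedure indicators in the propensity model are
#' estimable and matched outcome contrasts are not driven by unique
#' operations.
#'
#' @param records Patient table with a procedure category column.
#' @param floor Minimum category count to retain (default 50).
#' @param category Column name (default `"body_region"`).
#' @return List with `records` (filtered) and `excluded` (data.frame of
#'   category, count).
#' @export
exclude_rare_procedures <- function(records, floor = 50,
                                    category = "body_region") {
  counts <- table(records[[category]])
  rare <- names(counts)[counts < floor]
  excluded <- data.frame(category = rare,
                         count = as.integer(counts[rare]),
                         stringsAsFactors = FALSE)
  keep <- !(records[[category]] %in% rare)
  if (!any(keep)) stop("all procedure categories fall below the floor")
  list(records = records[keep, , drop = FALSE], excluded = excluded)
}

#' Fit a propensity-score model for the oxygen-duration exposure
#'
#' Logistic regression of the exposure on pre/intra-operative covariates
#' (post-PACU variables must not be admitted, or matching would control
#' away consequences of the exposure). Returns the fitted probability of
#' exposure per patient.
#'
#' @param exposure Binary exposure column name.
#' @param covariates Covariate term names (may include factor columns such
#'   as procedure body region).
#' @param data Patient table.
#' @return List with `scores` (per-row propensity in (0,1)) and `model`
#'   (the underlying `prc_model`).
#' @export
fit_propensity <- function(exposure, covariates, data) {
  model <- fit_logistic(exposure, covariates, data, diagnostics = FALSE)
  list(scores = as.numeric(stats::fitted(model$fit)), model = model)
}

#' Greedy 1:1 nearest-neighbor matching without replacement
#'
#' Walks the exposed group in descending propensity-score order; each
#' exposed patient takes the not-yet-used control with the smallest
#' absolute score difference (ties broken by lowest control index), and
#' that control leaves the pool. With a caliper set, pairs farther apart
#' than the caliper are discarded and the exposed patient goes unmatched.
#' The procedure is fully deterministic given scores and ordering.
#'
#' @param scores Propensity scores for all patients.
#' @param exposed Logical/0-1 exposure flags, same length.
#' @param ids Optional patient identifiers (default: integer indices).
#' @param caliper Maximum allowed |score difference| (`NULL` = none).
#' @param order `"descending"` (default) or `"random"` walk over the
#'   exposed group; random order uses the current RNG state.
#' @return Object of class `matched_cohort`: `pairs` (exposed id, control
#'   id, score gap), `unmatched_exposed`, `n_exposed`, `n_control`.
#' @export
nearest_neighbor_match <- function(scores, exposed, ids = NULL,
                                   caliper = NULL,
                                   order = c("descending", "random")) {
  order <- match.arg(order)
  exposed <- as.logical(exposed)
  if (!any(exposed) || all(exposed)) stop("both groups must be non-empty")
  if (is.null(ids)) ids <- seq_along(scores)
  e_idx <- which(exposed)
  c_idx <- which(!exposed)
  walk <- if (order == "descending") {
    e_idx[order(scores[e_idx], decreasing = TRUE)]
  } else {
    sample(e_idx)
  }
  available <- rep(TRUE, length(c_idx))
  pairs <- vector("list", length(walk))
  n_pairs <- 0L
  for (e in walk) {
    if (!any(available)) break
    gaps <- abs(scores[c_idx] - scores[e])
    gaps[!available] <- Inf
    best <- which.min(gaps)  # first minimum = lowest control index
    if (!is.null(caliper) && gaps[best] > caliper) next
    available[best] <- FALSE
    n_pairs <- n_pairs + 1L
    pairs[[n_pairs]] <- data.frame(
      exposed_id = ids[e], control_id = ids[c_idx[best]],
      exposed_score = scores[e], control_score = scores[c_idx[best]],
      gap = gaps[best], stringsAsFactors = FALSE)
  }
  pairs <- if (n_pairs > 0) do.call(rbind, pairs[seq_len(n_pairs)])
           else data.frame(exposed_id = ids[integer(0)],
                           control_id = ids[integer(0)],
                           exposed_score = numeric(0),
                           control_score = numeric(0), gap = numeric(0))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_exposed = setdiff(ids[e_idx], pairs$exposed_id),
                 n_exposed = length(e_idx), n_control = length(c_idx)),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("<matched_cohort>", nrow(x$pairs), "pairs from", x$n_exposed,
      "exposed /", x$n_control, "controls;",
      length(x$unmatched_exposed), "exposed unmatched\n")
  invisible(x)
}

#' Standardized mean difference between two groups
#'
#' Difference in means over the pooled standard deviation; for binary
#' variables, difference in proportions over the pooled binary SD.
#' Constant variables return 0 by convention.
#'
#' @param x Numeric (or 0/1) values.
#' @param group Logical/0-1 indicator (TRUE = exposed).
#' @return Scalar SMD (signed: exposed minus control).
#' @export
standardized_mean_difference <- function(x, group) {
  group <- as.logical(group)
  ok <- !is.na(x) & !is.na(group)
  x <- x[ok]; group <- group[ok]
  x1 <- x[group]; x0 <- x[!group]
  binary <- all(x %in% c(0, 1))
  if (binary) {
    p1 <- mean(x1); p0 <- mean(x0)
    pooled <- sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2)
    if (pooled == 0) return(0)
    (p1 - p0) / pooled
  } else {
    pooled <- sqrt((stats::var(x1) + stats::var(x0)) / 2)
    if (is.na(pooled) || pooled == 0) return(0)
    (mean(x1) - mean(x0)) / pooled
  }
}

#' Pre/post-match covariate balance table
#'
#' For each variable: group means (or proportions), the hypothesis-test p
#' (chi-square for binary, Mann-Whitney otherwise) and the standardized
#' mean difference, before matching (all patients) and after (matched
#' pairs only).
#'
#' @param matched A [nearest_neighbor_match()] result.
#' @param records Patient table with a `patient_id` column.
#' @param variables Variables to balance-check.
#' @param exposure Exposure column name.
#' @return Data.frame with one row per variable.
#' @export
balance_table <- function(matched, records, variables, exposure) {
  if (nrow(matched$pairs) == 0) stop("matched cohort is empty")
  matched_ids <- c(matched$pairs$exposed_id, matched$pairs$control_id)
  post <- records[records$patient_id %in% matched_ids, , drop = FALSE]
  one_pass <- function(dat) {
    grp <- as.logical(dat[[exposure]])
    lapply(variables, function(v) {
      x <- dat[[v]]
      smd <- standardized_mean_difference(x, grp)
      binary <- all(x[!is.na(x)] %in% c(0, 1))
      p <- tryCatch({
        if (binary) {
          chi_square_test(table(x, grp))$p_value
        } else {
          continuous_comparison(x, grp, method = "mann_whitney")$p_value
        }
      }, error = function(e) NA_real_)
      data.frame(variable = v,
                 mean_exposed = mean(x[grp], na.rm = TRUE),
                 mean_control = mean(x[!grp], na.rm = TRUE),
                 p_value = p, smd = smd, stringsAsFactors = FALSE)
    })
  }
  pre <- do.call(rbind, one_pass(records))
  pst <- do.call(rbind, one_pass(post))
  names(pre)[-1] <- paste0("pre_", names(pre)[-1])
  names(pst)[-1] <- paste0("post_", names(pst)[-1])
  out <- merge(pre, pst, by = "variable", sort = FALSE)
  rownames(out) <- NULL
  out
}

#' Secondary-outcome comparison on the matched cohort
#'
#' Continuous outcomes (charges, length of stay) are summarized as median
#' [IQR] per group with a Mann-Whitney p; binary outcomes (reintubation,
#' ventilatory support) as counts with the Woolf odds ratio and chi-square
#' p. Also returns the charge-by-oxygen-quartile summary for the unmatched
#' and matched cohorts.
#'
#' @param matched A [nearest_neighbor_match()] result.
#' @param records Patient table.
#' @param exposure Exposure column name.
#' @param continuous,binary Outcome column names of each type.
#' @param o2_quartile Optional oxygen-quartile column for the
#'   charge-by-quartile summary.
#' @param charges Charge column used for the quartile summary.
#' @return List with `continuous`, `binary` and (optionally)
#'   `charges_by_quartile` data.frames.
#' @export
matched_outcomes <- function(matched, records, exposure,
                             continuous = c("total_charges",
                                            "day_of_surgery_charges",
                                            "surgery_charges",
                                            "respiratory_charges",
                                            "los_days"),
                             binary = c("reintubation", "vent_support"),
                             o2_quartile = NULL,
                             charges = "total_charges") {
  matched_ids <- c(matched$pairs$exposed_id, matched$pairs$control_id)
  post <- records[records$patient_id %in% matched_ids, , drop = FALSE]
  grp <- as.logical(post[[exposure]])
  cont <- do.call(rbind, lapply(intersect(continuous, names(post)),
                                function(v) {
    cc <- tryCatch(continuous_comparison(post[[v]], grp),
                   error = function(e) NULL)
    if (is.null(cc)) return(NULL)
    s1 <- cc$summaries[["TRUE"]]; s0 <- cc$summaries[["FALSE"]]
    data.frame(outcome = v,
               exposed_median = s1$median, exposed_q25 = s1$q25,
               exposed_q75 = s1$q75,
               control_median = s0$median, control_q25 = s0$q25,
               control_q75 = s0$q75,
               p_value = cc$p_value, stringsAsFactors = FALSE)
  }))
  bin <- do.call(rbind, lapply(intersect(binary, names(post)),
                               function(v) {
    x <- post[[v]]
    a <- sum(x == 1 & grp, na.rm = TRUE)
    b <- sum(x == 1 & !grp, na.rm = TRUE)
    c_ <- sum(x == 0 & grp, na.rm = TRUE)
    d <- sum(x == 0 & !grp, na.rm = TRUE)
    est <- odds_ratio_woolf(a, b, c_, d)
    p <- tryCatch(chi_square_test(matrix(c(a, b, c_, d), 2))$p_value,
                  error = function(e) NA_real_)
    data.frame(outcome = v, exposed_events = a, control_events = b,
               or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
               p_value = p, stringsAsFactors = FALSE)
  }))
  out <- list(continuous = cont, binary = bin)
  if (!is.null(o2_quartile) && o2_quartile %in% names(records)) {
    by_q <- function(dat) {
      do.call(rbind, lapply(sort(unique(dat[[o2_quartile]])), function(q) {
        v <- dat[[charges]][dat[[o2_quartile]] == q]
        valid <- v[!is.na(v)]
        data.frame(quartile = q, median = stats::median(valid),
                   q25 = centile(valid, 0.25), q75 = centile(valid, 0.75),
                   valid_n = length(valid), total_n = length(v),
                   stringsAsFactors = FALSE)
      }))
    }
    out$charges_by_quartile <- list(unmatched = by_q(records),
                                    matched = by_q(post))
  }
  out
}
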