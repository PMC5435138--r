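#' Odds ratio with Woolf confidence interval from a 2x2 table
#'
#' Cells follow the epidemiological layout: `a` = outcome-positive exposed,
#' `b` = outcome-positive unexposed, `c` = outcome-negative exposed, `d` =
#' outcome-negative unexposed. OR = (a/b)/(c/d); the Woolf interval is
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero
#' the Haldane-Anscombe correction (0.5 added to every cell) is applied and
#' the result flagged.
#'
#' @param a,b,c,d Non-negative counts.
#' @param alpha Two-sided significance level (default 0.05).
#' @return List with `or`, `ci_low`, `ci_high`, `corrected` (logical) and
#'   `undefined` (logical, when a full margin is empty).
#' @export
odds_ratio_woolf <- function(a, b, c, d, alpha = 0.05) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("cell counts must be non-negative and non-missing")
  }
  if ((a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                corrected = FALSE, undefined = TRUE))
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a / b) / (c / d)
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       corrected = corrected, undefined = FALSE)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's statistic without continuity correction, with
#' `df = (r - 1)(c - 1)`; zero-margin rows/columns are dropped with a
#' warning before testing.
#'
#' @param tab Matrix of counts (at least 2x2 after dropping empty margins).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin row(s)/column(s) from contingency table")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("contingency table must be at least 2x2 after dropping empty margins")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Two-group comparison of a continuous variable
#'
#' Student t test or Mann-Whitney U test, with the group summaries used in
#' descriptive tables (mean, median, interquartile range).
#'
#' @param values Numeric vector.
#' @param group Two-level grouping vector.
#' @param method `"t"` or `"mann_whitney"`.
#' @return List with `statistic`, `p_value`, `method` and per-group
#'   `summaries` (n, mean, median, q25, q75).
#' @export
continuous_comparison <- function(values, group,
                                  method = c("mann_whitney", "t")) {
  method <- match.arg(method)
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- factor(group[ok])
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  split_vals <- split(values, group)
  if (any(vapply(split_vals, length, integer(1)) < 2)) {
    stop("each group needs at least two observations")
  }
  summaries <- lapply(split_vals, function(v) {
    list(n = length(v), mean = mean(v), median = stats::median(v),
         q25 = centile(v, 0.25), q75 = centile(v, 0.75))
  })
  if (stats::var(values) == 0) {
    warning("pooled data are constant; p set to 1")
    return(list(statistic = NA_real_, p_value = 1, method = method,
                summaries = summaries))
  }
  ht <- if (method == "t") {
    stats::t.test(split_vals[[1]], split_vals[[2]])
  } else {
    suppressWarnings(stats::wilcox.test(split_vals[[1]], split_vals[[2]],
                                        exact = FALSE, correct = FALSE))
  }
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       method = method, summaries = summaries)
}

#' Missingness audit of a patient table
#'
#' Reports per-variable missingness, flags variables above the 5% review
#' threshold, and, for flagged variables, the unadjusted 2x2 odds ratio of
#' the outcome between patients with missing and complete values — the
#' check that missingness is not outcome-informative.
#'
#' @param data Patient table.
#' @param variables Columns to audit (default: all except the outcome).
#' @param outcome Outcome column name (default `"early_prc"`).
#' @param flag_threshold Fractional missingness above which a variable is
#'   flagged (default 0.05).
#' @return Data.frame with `variable`, `pct_missing`, `flagged`, and for
#'   flagged variables the outcome-vs-missingness `or`, `ci_low`, `ci_high`.
#' @export
missingness_audit <- function(data, variables = NULL, outcome = "early_prc",
                              flag_threshold = 0.05) {
  if (is.null(variables)) variables <- setdiff(names(data), outcome)
  y <- data[[outcome]]
  rows <- lapply(variables, function(v) {
    miss <- is.na(data[[v]])
    pct <- 100 * mean(miss)
    flagged <- pct > 100 * flag_threshold
    or <- ci_lo <- ci_hi <- NA_real_
    if (flagged && !is.null(y)) {
      est <- odds_ratio_woolf(sum(y == 1 & miss, na.rm = TRUE),
                              sum(y == 1 & !miss, na.rm = TRUE),
                              sum(y == 0 & miss, na.rm = TRUE),
                              sum(y == 0 & !miss, na.rm = TRUE))
      or <- est$or; ci_lo <- est$ci_low; ci_hi <- est$ci_high
    }
    data.frame(variable = v, pct_missing = pct, flagged = flagged,
               or = or, ci_low = ci_lo, ci_high = ci_hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Table-1 style univariate comparison across outcome groups
#'
#' For each binary variable: counts and percentages by outcome group
#' (percentages on non-missing denominators), the Pearson chi-square p, the
#' unadjusted odds ratio with Woolf 95% CI, and percent missing. For
#' categorical variables with more than two levels only counts and the
#' chi-square p are reported (OR not applicable).
#'
#' @param data Patient table.
#' @param variables Character vector of variable names.
#' @param outcome Binary outcome column name.
#' @return Data.frame, one row per variable (or per level for
#'   multi-level variables, with the test on the variable's first row).
#' @export
univariate_table <- function(data, variables, outcome = "early_prc") {
  y <- data[[outcome]]
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    miss_pct <- 100 * mean(is.na(x))
    ok <- !is.na(x) & !is.na(y)
    xv <- x[ok]; yv <- y[ok]
    lv <- sort(unique(xv))
    if (length(lv) == 2 && all(lv %in% c(0, 1))) {
      a <- sum(yv == 1 & xv == 1); b <- sum(yv == 1 & xv == 0)
      c_ <- sum(yv == 0 & xv == 1); d <- sum(yv == 0 & xv == 0)
      est <- odds_ratio_woolf(a, b, c_, d)
      p <- tryCatch(chi_square_test(matrix(c(a, b, c_, d), 2))$p_value,
                    error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = NA_character_,
        n_outcome = a, pct_outcome = 100 * a / sum(yv == 1),
        n_control = c_, pct_control = 100 * c_ / sum(yv == 0),
        p_value = p, or = est$or, ci_low = est$ci_low,
        ci_high = est$ci_high, pct_missing = miss_pct,
        stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(xv), factor(yv, levels = c(0, 1)))
      p <- tryCatch(chi_square_test(tab)$p_value,
                    error = function(e) NA_real_)
      for (i in seq_along(rownames(tab))) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = rownames(tab)[i],
          n_outcome = tab[i, "1"],
          pct_outcome = 100 * tab[i, "1"] / sum(tab[, "1"]),
          n_control = tab[i, "0"],
          pct_control = 100 * tab[i, "0"] / sum(tab[, "0"]),
          p_value = if (i == 1) p else NA_real_,
          or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          pct_missing = if (i == 1) miss_pct else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render an odds ratio in Table-1 style
#'
#' One-decimal odds ratio and interval, e.g. `"3.0 (2.2-4.0)"`.
#'
#' @param or,ci_low,ci_high Estimates from [odds_ratio_woolf()].
#' @return Character scalar.
#' @export
format_or <- function(or, ci_low, ci_high) {
  if (is.na(or)) return("N/A")
  sprintf("%.1f (%.1f-%.1f)", or, ci_low, ci_high)
}
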