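#' Fit a logistic regression with full diagnostics
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, relative deviance tolerance 1e-8, at most 100 iterations) with
#' the diagnostics battery attached: c-statistic with Hanley-McNeil
#' standard error, Hosmer-Lemeshow test over risk deciles, per-term
#' variance inflation factors, condition indices of the scaled design, and
#' the omnibus likelihood-ratio test against the intercept-only model.
#'
#' @param outcome Name of the binary outcome column.
#' @param terms Character vector of model terms (columns of `data`; factor
#'   columns expand to indicator sets). Empty fits the intercept-only model.
#' @param data Data.frame.
#' @param epsilon,maxit IRLS convergence tolerance and iteration cap.
#' @param diagnostics Compute the diagnostics battery (default `TRUE`).
#' @param separation_bound Absolute coefficient magnitude treated as
#'   quasi-separation (default 15).
#' @return Object of class `prc_model`: the glm fit, a per-term coefficient
#'   table (estimate, SE, Wald p, AOR, 95% CI), log-likelihood and
#'   diagnostics.
#' @export
fit_logistic <- function(outcome, terms, data, epsilon = 1e-8, maxit = 100,
                         diagnostics = TRUE, separation_bound = 15) {
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  if (length(unique(y[!is.na(y)])) != 2) {
    stop("outcome must be binary with both classes present")
  }
  form <- if (length(terms) == 0) {
    stats::reformulate("1", response = outcome)
  } else {
    stats::reformulate(terms, response = outcome)
  }
  fit <- stats::glm(form, family = stats::binomial(), data = data,
                    control = stats::glm.control(epsilon = epsilon,
                                                 maxit = maxit))
  if (nrow(data) <= length(stats::coef(fit))) {
    stop("more coefficients than observations")
  }
  if (!fit$converged) {
    stop(sprintf("IRLS did not converge within %d iterations (last deviance %.6g)",
                 maxit, fit$deviance))
  }
  est <- stats::coef(fit)
  sep <- which(abs(est) > separation_bound)
  if (length(sep) > 0) {
    stop("quasi-separation detected for term(s): ",
         paste(names(est)[sep], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  coef_table <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    wald_p = sm[, "Pr(>|z|)"],
    aor = exp(sm[, "Estimate"]),
    ci_low = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
    ci_high = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
    stringsAsFactors = FALSE)
  rownames(coef_table) <- NULL
  out <- structure(
    list(fit = fit, coef_table = coef_table,
         loglik = as.numeric(stats::logLik(fit)),
         outcome = outcome, terms = terms,
         diagnostics = NULL, ledger = NULL),
    class = "prc_model")
  if (diagnostics) out$diagnostics <- model_diagnostics(out)
  out
}

#' @export
print.prc_model <- function(x, ...) {
  cat("<prc_model>", x$outcome, "~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1", "\n")
  ct <- x$coef_table
  ct$aor <- round(ct$aor, 3)
  ct$ci_low <- round(ct$ci_low, 3)
  ct$ci_high <- round(ct$ci_high, 3)
  ct$wald_p <- signif(ct$wald_p, 3)
  print(ct[, c("term", "aor", "ci_low", "ci_high", "wald_p")],
        row.names = FALSE)
  if (!is.null(x$diagnostics)) {
    cat(sprintf("c-statistic %.3f (SE %.3f); Hosmer-Lemeshow p %.3f; omnibus p %.3g\n",
                x$diagnostics$c_statistic, x$diagnostics$c_se,
                x$diagnostics$hosmer_lemeshow$p_value,
                x$diagnostics$omnibus$p_value))
  }
  invisible(x)
}

#' Concordance statistic (c-statistic) with Hanley-McNeil standard error
#'
#' Probability that a randomly chosen case carries a higher fitted risk
#' than a randomly chosen control; ties count one half. Computed from mean
#' case ranks; the standard error uses the Hanley-McNeil approximation.
#'
#' @param scores Fitted probabilities or any risk scores.
#' @param outcome Binary 0/1 outcome.
#' @return List with `c_statistic`, `se`, `n_cases`, `n_controls`.
#' @export
c_statistic <- function(scores, outcome) {
  ok <- !is.na(scores) & !is.na(outcome)
  scores <- scores[ok]; outcome <- outcome[ok]
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes required")
  r <- rank(scores, ties.method = "average")
  cstat <- (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- cstat / (2 - cstat)
  q2 <- 2 * cstat^2 / (1 + cstat)
  se <- sqrt((cstat * (1 - cstat) + (n1 - 1) * (q1 - cstat^2) +
                (n0 - 1) * (q2 - cstat^2)) / (n1 * n0))
  list(c_statistic = cstat, se = se, n_cases = n1, n_controls = n0)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into deciles of fitted risk (duplicate quantile
#' breaks collapse, with a warning when fewer than the requested groups
#' survive) and compares observed to expected events per group;
#' `df = groups - 2`.
#'
#' @param fitted Fitted probabilities.
#' @param outcome Binary 0/1 outcome.
#' @param groups Target number of risk groups (default 10).
#' @return List with `statistic`, `df`, `p_value`, `n_groups`, and the
#'   per-group `table`.
#' @export
hosmer_lemeshow <- function(fitted, outcome, groups = 10) {
  ok <- !is.na(fitted) & !is.na(outcome)
  fitted <- fitted[ok]; outcome <- outcome[ok]
  breaks <- unique(stats::quantile(fitted, probs = seq(0, 1,
                                                       length.out = groups + 1),
                                   type = 7))
  if (length(breaks) < groups + 1) {
    warning("tied risk values: Hosmer-Lemeshow groups collapsed to ",
            length(breaks) - 1)
  }
  if (length(breaks) < 4) {
    # fewer than 3 groups leaves no degrees of freedom
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                n_groups = length(breaks) - 1, table = NULL))
  }
  g <- cut(fitted, breaks = breaks, include.lowest = TRUE)
  obs1 <- tapply(outcome, g, sum)
  n <- tapply(outcome, g, length)
  exp1 <- tapply(fitted, g, sum)
  obs0 <- n - obs1
  exp0 <- n - exp1
  stat <- sum((obs1 - exp1)^2 / exp1 + (obs0 - exp0)^2 / exp0)
  df <- length(levels(g)) - 2
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       n_groups = length(levels(g)),
       table = data.frame(group = levels(g), n = as.integer(n),
                          observed = as.integer(obs1), expected = exp1))
}

#' Variance inflation factors from a design matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column j
#' on the remaining predictors (intercept included in the auxiliary fits).
#'
#' @param X Numeric design matrix of predictors (no intercept column).
#' @return Named numeric vector; single-column designs return 1, constant
#'   columns `NA`.
#' @export
vif_from_design <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  out <- stats::setNames(rep(NA_real_, p), colnames(X))
  variable <- apply(X, 2, stats::var) > 0
  if (sum(variable) == 1) {
    out[variable] <- 1
    return(out)
  }
  for (j in which(variable)) {
    others <- X[, setdiff(which(variable), j), drop = FALSE]
    r2 <- summary(stats::lm(X[, j] ~ others))$r.squared
    out[j] <- 1 / (1 - r2)
  }
  out
}

#' Condition indices of a scaled design matrix
#'
#' Columns (including the intercept) are scaled to unit Euclidean length;
#' condition indices are the ratios of the largest singular value to each
#' singular value. Values above 30 conventionally signal collinearity
#' worth inspecting.
#'
#' @param X Design matrix including the intercept column.
#' @return Numeric vector of condition indices, decreasing from the
#'   largest.
#' @export
condition_indices <- function(X) {
  X <- as.matrix(X)
  norms <- sqrt(colSums(X^2))
  norms[norms == 0] <- 1
  Xs <- sweep(X, 2, norms, "/")
  d <- svd(Xs, nu = 0, nv = 0)$d
  max(d) / d
}

#' Diagnostics battery for a fitted logistic model
#'
#' @param model A `prc_model` or glm fit.
#' @return List with `c_statistic`, `c_se`, `hosmer_lemeshow`, `vif`,
#'   `condition_indices` and `omnibus` (likelihood-ratio test vs the
#'   intercept-only model, df = number of non-intercept coefficients).
#' @export
model_diagnostics <- function(model) {
  fit <- if (inherits(model, "prc_model")) model$fit else model
  y <- fit$y
  p <- stats::fitted(fit)
  cs <- c_statistic(p, y)
  hl <- tryCatch(suppressWarnings(hosmer_lemeshow(p, y)),
                 error = function(e) list(statistic = NA_real_,
                                          df = NA_integer_,
                                          p_value = NA_real_))
  X <- stats::model.matrix(fit)
  pred <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  vif <- if (ncol(pred) > 0) vif_from_design(pred) else numeric(0)
  ci <- condition_indices(X)
  lr <- fit$null.deviance - fit$deviance
  df <- fit$df.null - fit$df.residual
  list(c_statistic = cs$c_statistic, c_se = cs$se,
       hosmer_lemeshow = hl, vif = vif, condition_indices = ci,
       omnibus = list(statistic = lr, df = df,
                      p_value = if (df > 0)
                        stats::pchisq(lr, df, lower.tail = FALSE)
                      else NA_real_))
}

#' Linearity-of-logits coding decision for an ordinal covariate
#'
#' Computes the empirical logit of the outcome at each level; the variable
#' keeps ordinal coding when the per-level logit steps are monotone and
#' near-constant (max deviation of a step from the mean step within
#' `tolerance`), and is recoded as indicator variables otherwise. Levels
#' with zero events receive a 0.5 continuity correction and are flagged.
#'
#' @param x Ordinal covariate (numeric or ordered levels).
#' @param outcome Binary 0/1 outcome.
#' @param tolerance Allowed deviation of logit steps from their mean
#'   (default 0.15 on the log-odds scale).
#' @return List with `decision` (`"ordinal"` or `"indicator"`), per-level
#'   `logits` (for plotting), `steps`, and `corrected` flag.
#' @export
linearity_of_logits <- function(x, outcome, tolerance = 0.15) {
  ok <- !is.na(x) & !is.na(outcome)
  x <- x[ok]; outcome <- outcome[ok]
  lv <- sort(unique(x))
  events <- vapply(lv, function(l) sum(outcome[x == l] == 1), numeric(1))
  totals <- vapply(lv, function(l) sum(x == l), numeric(1))
  nonevents <- totals - events
  corrected <- any(events == 0 | nonevents == 0)
  if (corrected) {
    events <- events + 0.5
    nonevents <- nonevents + 0.5
  }
  logits <- stats::setNames(log(events / nonevents), as.character(lv))
  if (length(lv) < 3) {
    return(list(decision = "ordinal", logits = logits, steps = numeric(0),
                corrected = corrected))
  }
  steps <- diff(logits)
  monotone <- all(steps >= 0) || all(steps <= 0)
  flat_enough <- max(abs(steps - mean(steps))) <= tolerance
  list(decision = if (monotone && flat_enough) "ordinal" else "indicator",
       logits = logits, steps = unname(steps), corrected = corrected)
}

## Wald p per model term (min across a term's coefficients, so factor
## terms are judged by their strongest contrast).
term_wald_p <- function(model, term) {
  fit <- model$fit
  asgn <- attr(stats::model.matrix(fit), "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  idx <- which(asgn == match(term, labels))
  min(model$coef_table$wald_p[idx])
}

## Coefficient rows belonging to a set of model terms.
term_coef_names <- function(model, term_set) {
  fit <- model$fit
  asgn <- attr(stats::model.matrix(fit), "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  colnames(stats::model.matrix(fit))[asgn %in% match(term_set, labels)]
}

#' Change-in-estimate backward covariate selection
#'
#' Starting from the fully specified model, repeatedly removes the
#' removable covariate with the largest Wald p-value and measures the
#' change in the primary exposure's estimate as
#' `|ln(AOR_current / AOR_reduced)|` (the maximum over the exposure's
#' coefficients when it spans several). A change above `threshold` means
#' the covariate is a confounder of the exposure-outcome relationship: it
#' is restored and — under the default stopping rule — the whole procedure
#' stops at this first retained covariate. Smaller changes drop the
#' covariate permanently. The primary exposure is never eligible for
#' removal. Every step is recorded in a ledger.
#'
#' @param outcome Binary outcome column name.
#' @param exposure Character vector of primary exposure term(s), never
#'   removed.
#' @param candidates Candidate covariate terms, in priority order (ties in
#'   Wald p are broken by this order).
#' @param data Data.frame.
#' @param threshold Change-in-estimate threshold on the log-AOR scale
#'   (default 0.10, i.e. a 10% change).
#' @param sequential At `TRUE` (default) the reference model for each step
#'   is the current model; at `FALSE` every removal is judged against the
#'   original full model.
#' @param stop_at_first At `TRUE` (default) the procedure stops at the
#'   first retained covariate; at `FALSE` it continues past it, keeping the
#'   covariate but testing the rest.
#' @param diagnostics Compute diagnostics on the final model.
#' @return A `prc_model` for the final model with `$ledger`: one row per
#'   step (`term`, `wald_p`, `delta`, `action`).
#' @export
change_in_estimate_selection <- function(outcome, exposure, candidates,
                                         data, threshold = 0.10,
                                         sequential = TRUE,
                                         stop_at_first = TRUE,
                                         diagnostics = TRUE) {
  current <- candidates
  retained <- character(0)
  ledger <- data.frame(step = integer(0), term = character(0),
                       wald_p = numeric(0), delta = numeric(0),
                       action = character(0), stringsAsFactors = FALSE)
  full_model <- tryCatch(
    fit_logistic(outcome, c(exposure, current), data, diagnostics = FALSE),
    error = function(e) stop("full model failed to fit: ",
                             conditionMessage(e)))
  reference <- full_model
  step <- 0L
  exposure_est <- function(model) {
    nm <- term_coef_names(model, exposure)
    stats::setNames(model$coef_table$estimate[
      match(nm, model$coef_table$term)], nm)
  }
  repeat {
    removable <- setdiff(current, retained)
    if (length(removable) == 0) break
    base_model <- if (sequential) reference else full_model
    base_terms <- if (sequential) current else candidates
    ps <- vapply(removable, function(t) term_wald_p(base_model, t),
                 numeric(1))
    worst <- removable[which.max(ps)]  # which.max is first-max: list order
    step <- step + 1L
    reduced <- tryCatch(
      fit_logistic(outcome, c(exposure, setdiff(base_terms, worst)), data,
                   diagnostics = FALSE),
      error = function(e) NULL)
    if (is.null(reduced)) {
      ledger <- rbind(ledger, data.frame(
        step = step, term = worst, wald_p = max(ps), delta = NA_real_,
        action = "fit_failure", stringsAsFactors = FALSE))
      warning("selection aborted at step ", step,
              ": reduced model failed to fit; partial ledger returned")
      break
    }
    e_full <- exposure_est(base_model)
    e_red <- exposure_est(reduced)
    delta <- max(abs(e_full[names(e_red)] - e_red))
    if (delta > threshold) {
      retained <- c(retained, worst)
      ledger <- rbind(ledger, data.frame(
        step = step, term = worst, wald_p = max(ps), delta = delta,
        action = "retained", stringsAsFactors = FALSE))
      if (stop_at_first) break
    } else {
      current <- setdiff(current, worst)
      ledger <- rbind(ledger, data.frame(
        step = step, term = worst, wald_p = max(ps), delta = delta,
        action = "dropped", stringsAsFactors = FALSE))
      if (sequential) reference <- reduced
    }
  }
  final <- fit_logistic(outcome, c(exposure, current), data,
                        diagnostics = diagnostics)
  final$ledger <- ledger
  final$retained_candidates <- current
  final$dropped_candidates <- setdiff(candidates, current)
  final$exposure <- exposure
  final
}

#' Exposure-by-stratum interaction analysis
#'
#' Fits a logistic model with the exposure, the stratifier, their product
#' term and any adjustment covariates, and reports the 2x2 matrix of cell
#' adjusted odds ratios against the joint reference cell (exposure absent,
#' lower-risk stratum) with Wald p-values. Stratified analyses are
#' indicated when the product-term p falls below `alpha`.
#'
#' @param outcome,exposure,stratifier Column names; exposure and
#'   stratifier must be binary 0/1.
#' @param covariates Additional adjustment terms.
#' @param data Data.frame.
#' @param alpha Interaction significance threshold (default 0.05).
#' @return List of class `interaction_result` with `aor_matrix`,
#'   `p_matrix`, `interaction_p`, `stratify` flag and `degenerate` flag.
#' @export
interaction_analysis <- function(outcome, exposure, stratifier,
                                 covariates = character(0), data,
                                 alpha = 0.05) {
  cells <- table(data[[exposure]], data[[stratifier]])
  if (!all(dim(cells) == c(2, 2)) || any(cells == 0)) {
    return(structure(list(aor_matrix = NULL, p_matrix = NULL,
                          interaction_p = NA_real_, stratify = NA,
                          degenerate = TRUE),
                     class = "interaction_result"))
  }
  prod_term <- paste0(exposure, ":", stratifier)
  model <- fit_logistic(outcome,
                        c(exposure, stratifier, prod_term, covariates),
                        data, diagnostics = FALSE)
  fit <- model$fit
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  nm_e <- exposure
  nm_s <- stratifier
  nm_i <- intersect(c(paste0(exposure, ":", stratifier),
                      paste0(stratifier, ":", exposure)), names(b))
  combo <- function(terms) {
    w <- stats::setNames(rep(0, length(b)), names(b))
    w[terms] <- 1
    est <- sum(w * b)
    se <- sqrt(drop(t(w) %*% V %*% w))
    c(aor = exp(est),
      p = 2 * stats::pnorm(-abs(est / se)))
  }
  c10 <- combo(nm_e)                 # exposed, lower-risk stratum
  c01 <- combo(nm_s)                 # unexposed, higher-risk stratum
  c11 <- combo(c(nm_e, nm_s, nm_i))  # exposed, higher-risk stratum
  aor <- matrix(c(1, c01["aor"], c10["aor"], c11["aor"]), 2, 2,
                byrow = TRUE,
                dimnames = list(exposure = c("0", "1"),
                                stratum = c("0", "1")))
  pmat <- matrix(c(NA, c01["p"], c10["p"], c11["p"]), 2, 2, byrow = TRUE,
                 dimnames = dimnames(aor))
  ip <- model$coef_table$wald_p[match(nm_i, model$coef_table$term)]
  structure(list(aor_matrix = aor, p_matrix = pmat,
                 interaction_p = ip, stratify = ip < alpha,
                 degenerate = FALSE, model = model),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<interaction_result> degenerate (empty exposure x stratum cell)\n")
    return(invisible(x))
  }
  cat("<interaction_result> interaction p =", signif(x$interaction_p, 3),
      "- stratify:", x$stratify, "\n")
  print(round(x$aor_matrix, 3))
  invisible(x)
}

#' Stratified change-in-estimate models
#'
#' Runs the full selection pipeline independently within each level of the
#' stratifier; a failure in one stratum is isolated and reported without
#' blocking the other.
#'
#' @inheritParams change_in_estimate_selection
#' @param stratifier Column name defining the strata.
#' @return Named list of `prc_model` (or error condition) per stratum.
#' @export
stratified_models <- function(outcome, exposure, candidates, data,
                              stratifier, threshold = 0.10, ...) {
  levels <- sort(unique(data[[stratifier]]))
  out <- lapply(levels, function(lv) {
    sub <- data[data[[stratifier]] == lv & !is.na(data[[stratifier]]), ,
                drop = FALSE]
    tryCatch(
      change_in_estimate_selection(outcome, exposure, candidates, sub,
                                   threshold = threshold, ...),
      error = function(e) e)
  })
  names(out) <- paste0(stratifier, "=", levels)
  out
}
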