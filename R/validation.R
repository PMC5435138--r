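#' Parameter-recovery simulation for the exposure effect
#'
#' Repeatedly simulates tabular cohorts from a logistic outcome model with
#' a known exposure log-odds, refits the correctly specified model, and
#' summarizes bias and 95% confidence-interval coverage of the exposure
#' coefficient. This is the package's substitute for re-estimating the
#' published adjusted odds ratios, whose source data are not available:
#' the modeling stack is validated against a generating mechanism with
#' known truth instead.
#'
#' @param n_replicates Number of simulated cohorts (default 100).
#' @param n Patients per cohort (default 20000).
#' @param beta_exposure True exposure log-odds (default 0.7, an adjusted
#'   odds ratio of about 2).
#' @param intercept Outcome model intercept; the default gives an outcome
#'   prevalence near 2%.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List with `mean_estimate`, `mean_bias`, `coverage_pct`,
#'   `estimates`, `n`, `n_replicates`.
#' @export
recovery_simulation <- function(n_replicates = 100, n = 20000,
                                beta_exposure = 0.7, intercept = -4.2,
                                seed = 1) {
  est <- se <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    dat <- simulate_outcome_cohort(
      n,
      c(intercept = intercept, exposure = beta_exposure, copd = 1.0,
        renal_disease = 0.9),
      c(copd = 0.06, renal_disease = 0.09),
      exposure_model = 0.15, seed = seed + r)
    m <- fit_logistic("outcome", c("exposure", "copd", "renal_disease"),
                      dat, diagnostics = FALSE)
    i <- match("exposure", m$coef_table$term)
    est[r] <- m$coef_table$estimate[i]
    se[r] <- m$coef_table$se[i]
  }
  z <- stats::qnorm(0.975)
  covered <- (est - z * se) <= beta_exposure & beta_exposure <= (est + z * se)
  list(mean_estimate = mean(est), mean_bias = mean(est) - beta_exposure,
       coverage_pct = 100 * mean(covered), estimates = est,
       n = n, n_replicates = n_replicates)
}

#' Selection-correctness simulation for the change-in-estimate procedure
#'
#' Plants a strong confounder (drives both exposure assignment and the
#' outcome) and a pure-noise covariate, runs the change-in-estimate
#' selection on each replicate, and counts how often the confounder is
#' retained and the noise covariate dropped.
#'
#' @inheritParams recovery_simulation
#' @return List with `confounder_retained_pct`, `noise_dropped_pct`,
#'   `n`, `n_replicates`.
#' @export
selection_simulation <- function(n_replicates = 100, n = 20000, seed = 1) {
  kept <- dropped <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    dat <- simulate_outcome_cohort(
      n,
      c(intercept = -4.5, exposure = 0.7, conf = 1.5, noise = 0),
      c(conf = 0.35, noise = 0.30),
      exposure_model = c(intercept = -2.2, conf = 1.5), seed = seed + r)
    sel <- tryCatch(
      change_in_estimate_selection("outcome", "exposure",
                                   c("conf", "noise"), dat,
                                   diagnostics = FALSE),
      error = function(e) NULL)
    if (is.null(sel)) next
    kept[r] <- "conf" %in% sel$retained_candidates
    dropped[r] <- "noise" %in% sel$dropped_candidates
  }
  list(confounder_retained_pct = 100 * mean(kept),
       noise_dropped_pct = 100 * mean(dropped),
       n = n, n_replicates = n_replicates)
}

#' Size and power of the interaction-driven stratification decision
#'
#' Simulates cohorts with and without a true exposure-by-stratum product
#' term and records how often the interaction test (Wald p < 0.05) calls
#' for stratified analyses: the false-stratification rate under the null
#' (nominal 5%) and the detection rate under the alternative.
#'
#' @inheritParams recovery_simulation
#' @param interaction_beta True product-term log-odds under the
#'   alternative (default 0.6).
#' @return List with `null_stratify_rate_pct`, `power_pct`, `n`,
#'   `n_replicates`.
#' @export
interaction_simulation <- function(n_replicates = 100, n = 20000,
                                   interaction_beta = 0.6, seed = 1) {
  one_rate <- function(beta_int, seed0) {
    flags <- logical(n_replicates)
    for (r in seq_len(n_replicates)) {
      dat <- with_seed(seed0 + r, {
        e <- stats::rbinom(n, 1, 0.3)
        s <- stats::rbinom(n, 1, 0.4)
        lp <- -3.5 + 0.5 * e + 0.4 * s + beta_int * e * s
        data.frame(outcome = stats::rbinom(n, 1, stats::plogis(lp)),
                   exposure = e, strat = s)
      })
      ia <- tryCatch(interaction_analysis("outcome", "exposure", "strat",
                                          data = dat),
                     error = function(e) NULL)
      flags[r] <- !is.null(ia) && isTRUE(ia$stratify)
    }
    100 * mean(flags)
  }
  list(null_stratify_rate_pct = one_rate(0, seed),
       power_pct = one_rate(interaction_beta, seed + 100000),
       n = n, n_replicates = n_replicates)
}
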