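#' Simulation configuration for a synthetic PACU cohort
#'
#' Bundles every parameter of the synthetic data-generating mechanism:
#' per-minute SpO2 dynamics with episodic desaturation events, the nurse
#' oxygen-response loop, covariate prevalences, a logistic outcome model
#' with known coefficients, and log-normal charge distributions by oxygen
#' duration stratum. The same seed and config always reproduce the same
#' cohort, and growing the cohort never reshuffles existing patients
#' (per-patient substreams are seeded by a stable hash of the patient id).
#'
#' @param n_patients Cohort size (>= 1).
#' @param seed Master integer seed.
#' @param pacu_duration_min Monitored PACU stay in minutes (default 120).
#' @param short_stay_prob Probability a patient leaves PACU early, which
#'   exercises the missing-measure pathway downstream (default 0).
#' @param short_stay_range Range of early-departure stay lengths (minutes).
#' @param baseline_spo2_mean Baseline saturation in percent.
#' @param baseline_spo2_sd Per-minute Gaussian measurement noise (percent).
#' @param event_rate_by_phenotype Desaturation events per hour for the low,
#'   moderate and high OSA-risk strata.
#' @param event_depth_mean,event_depth_sd Gaussian event depth (% drop).
#' @param event_duration_mean Mean event duration in minutes (exponential).
#' @param alarm_threshold Monitor alarm threshold in percent (default 90).
#' @param nurse_response_delay Consecutive minutes below the alarm threshold
#'   before the nurse starts oxygen (default 2).
#' @param o2_uplift Percent added to SpO2 while oxygen is on.
#' @param o2_washout Minutes oxygen stays on after the event ends; long
#'   washouts create the long-oxygen-duration phenotype (default 10).
#' @param arrival_o2_prob Probability the patient arrives in PACU already
#'   on supplemental oxygen (routine after general anesthesia).
#' @param arrival_o2_duration_mean Mean minutes of arrival oxygen
#'   (exponential); spreads the oxygen-duration fractions continuously.
#' @param manual_roomair_probability Probability that a qualifying oxygen-off
#'   epoch (>= 5 min) receives a charted manual room-air entry.
#' @param psap_probs Probabilities of the low/moderate/high OSA-risk strata.
#' @param covariate_prevalences Named Bernoulli prevalences for the binary
#'   covariates.
#' @param outcome_coefficients Named log-odds (including `intercept`) of the
#'   generating outcome model. Terms may reference any configured covariate,
#'   `nadir_low` (nadir < `truth_nadir_cut`), or `o2_quartile` (the oxygen
#'   duration quartile as 0..3 above the reference).
#' @param truth_nadir_cut Saturation below which the generating model calls
#'   the patient nadir-desaturated (default 89%).
#' @param charge_meanlog,charge_sdlog Log-normal total-charge parameters by
#'   oxygen-duration quartile (<30, 31-60, 61-90, >90 min at a 120-min stay).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500,
                       seed = 1L,
                       pacu_duration_min = 120L,
                       short_stay_prob = 0,
                       short_stay_range = c(20L, 119L),
                       baseline_spo2_mean = 97,
                       baseline_spo2_sd = 1,
                       event_rate_by_phenotype = c(low = 0.5, moderate = 1.5,
                                                   high = 3),
                       event_depth_mean = 10,
                       event_depth_sd = 4,
                       event_duration_mean = 3,
                       alarm_threshold = 90,
                       nurse_response_delay = 2L,
                       o2_uplift = 5,
                       o2_washout = 10L,
                       arrival_o2_prob = 0.85,
                       arrival_o2_duration_mean = 40,
                       manual_roomair_probability = 0.3,
                       psap_probs = c(low = 0.48, moderate = 0.44,
                                      high = 0.08),
                       covariate_prevalences = c(
                         copd = 0.06, renal_disease = 0.09, chf = 0.03,
                         liver_disease = 0.06, neuro_disease = 0.13,
                         steroid = 0.04, pneumonia = 0.03, pulm_htn = 0.01,
                         sepsis = 0.01, smoking = 0.13, preop_opioid = 0.25,
                         asa_high = 0.03, naloxone = 0.006, pca = 0.001,
                         high_dose_rocuronium = 0.01),
                       outcome_coefficients = c(
                         intercept = -5.8, nadir_low = 0.7, o2_quartile = 0.35,
                         copd = 1.0, renal_disease = 0.9, sepsis = 1.2,
                         naloxone = 2.2, pca = 2.3, asa_high = 1.4),
                       truth_nadir_cut = 89,
                       charge_meanlog = c(9.23, 9.40, 9.45, 9.49),
                       charge_sdlog = c(0.56, 0.57, 0.73, 0.79)) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              pacu_duration_min = as.integer(pacu_duration_min),
              short_stay_prob = short_stay_prob,
              short_stay_range = as.integer(short_stay_range),
              baseline_spo2_mean = baseline_spo2_mean,
              baseline_spo2_sd = baseline_spo2_sd,
              event_rate_by_phenotype = event_rate_by_phenotype,
              event_depth_mean = event_depth_mean,
              event_depth_sd = event_depth_sd,
              event_duration_mean = event_duration_mean,
              alarm_threshold = alarm_threshold,
              nurse_response_delay = as.integer(nurse_response_delay),
              o2_uplift = o2_uplift, o2_washout = as.integer(o2_washout),
              arrival_o2_prob = arrival_o2_prob,
              arrival_o2_duration_mean = arrival_o2_duration_mean,
              manual_roomair_probability = manual_roomair_probability,
              psap_probs = psap_probs,
              covariate_prevalences = covariate_prevalences,
              outcome_coefficients = outcome_coefficients,
              truth_nadir_cut = truth_nadir_cut,
              charge_meanlog = charge_meanlog, charge_sdlog = charge_sdlog)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$short_stay_prob, cfg$manual_roomair_probability,
             cfg$arrival_o2_prob, cfg$psap_probs, cfg$covariate_prevalences)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (any(cfg$event_rate_by_phenotype < 0)) stop("event rates must be >= 0")
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  if (!setequal(names(cfg$event_rate_by_phenotype),
                c("low", "moderate", "high"))) {
    stop("event_rate_by_phenotype needs low/moderate/high entries")
  }
  if (abs(sum(cfg$psap_probs) - 1) > 1e-8) stop("psap_probs must sum to 1")
  allowed <- c("intercept", "nadir_low", "o2_quartile",
               names(cfg$covariate_prevalences))
  unknown <- setdiff(names(cfg$outcome_coefficients), allowed)
  if (length(unknown) > 0) {
    stop("outcome_coefficients reference unknown term(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!"intercept" %in% names(cfg$outcome_coefficients)) {
    stop("outcome_coefficients must include an intercept")
  }
  invisible(cfg)
}

## Run code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

## Stable 31-ary string hash into [0, 2^31 - 19), mixed with the master
## seed; keeps per-patient substreams fixed when the cohort grows.
stable_hash <- function(x, seed = 0L) {
  h <- as.double(seed %% 2147483629)
  for (b in utf8ToInt(as.character(x))) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

## Latent desaturation events: homogeneous Poisson onsets over [0, total),
## exponential durations, Gaussian depths (floored at 0).
draw_desat_events <- function(rate_per_hr, total_min, duration_mean,
                              depth_mean, depth_sd) {
  n <- stats::rpois(1, rate_per_hr * total_min / 60)
  if (n == 0) {
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      depth = numeric(0)))
  }
  onset <- sort(stats::runif(n, 0, total_min))
  duration <- stats::rexp(n, rate = 1 / duration_mean)
  depth <- pmax(0, stats::rnorm(n, depth_mean, depth_sd))
  data.frame(onset = onset, duration = duration, depth = depth)
}

#' Generate one synthetic PACU oximetry stream
#'
#' Simulates a per-minute SpO2 trace for one patient: a noisy baseline,
#' episodic desaturation events drawn from a Poisson process at the OSA-risk
#' stratum's rate, and a nurse response loop — once the displayed saturation
#' has been below the alarm threshold for `nurse_response_delay` consecutive
#' minutes, supplemental oxygen turns on (adding `o2_uplift`) and stays on
#' until the event has ended plus a washout period. Values are clipped to
#' [60, 100] and rounded to integers, as clinical monitors report. Oxygen-off
#' epochs of at least five minutes may receive a charted manual room-air
#' entry.
#'
#' @param phenotype OSA-risk stratum: `"low"`, `"moderate"` or `"high"`.
#' @param config A [sim_config()].
#' @param substream_seed Integer seed for this patient's substream.
#' @param patient_id Identifier stored on the stream.
#' @param stay_min Optional stay length override (minutes).
#' @return List with `stream` (an [oximetry_stream()]) and `events` (the
#'   latent event table, part of the simulation truth).
#' @export
generate_stream <- function(phenotype, config, substream_seed,
                            patient_id = "P000001", stay_min = NULL) {
  if (!is.character(phenotype) || length(phenotype) != 1 ||
      !phenotype %in% c("low", "moderate", "high")) {
    stop("phenotype must be one of \"low\", \"moderate\", \"high\"")
  }
  validate_sim_config(config)
  with_seed(substream_seed, {
    total <- if (is.null(stay_min)) config$pacu_duration_min
             else as.integer(stay_min)
    events <- draw_desat_events(config$event_rate_by_phenotype[[phenotype]],
                                total, config$event_duration_mean,
                                config$event_depth_mean, config$event_depth_sd)
    minutes <- seq_len(total) - 1L
    depth <- vapply(minutes, function(m) {
      sum(events$depth[events$onset <= m & m < events$onset + events$duration])
    }, numeric(1))
    raw <- config$baseline_spo2_mean +
      (if (config$baseline_spo2_sd > 0)
         stats::rnorm(total, 0, config$baseline_spo2_sd) else 0) - depth
    spo2 <- integer(total)
    o2_flag <- logical(total)
    # most patients arrive on supplemental oxygen; modelled as an initial
    # "washout" that the event/washout machinery then runs down
    o2_on <- stats::runif(1) < config$arrival_o2_prob
    below_run <- 0L
    washout <- if (o2_on) {
      max(1L, as.integer(round(stats::rexp(1, 1 / config$arrival_o2_duration_mean))))
    } else 0L
    for (i in seq_len(total)) {
      val <- raw[i] + if (o2_on) config$o2_uplift else 0
      disp <- as.integer(round(min(100, max(60, val))))
      spo2[i] <- disp
      o2_flag[i] <- o2_on
      below_run <- if (disp < config$alarm_threshold) below_run + 1L else 0L
      if (!o2_on && below_run >= config$nurse_response_delay) {
        o2_on <- TRUE
        washout <- config$o2_washout
      } else if (o2_on) {
        if (depth[i] > 0) {
          washout <- config$o2_washout
        } else {
          washout <- washout - 1L
          if (washout <= 0L) o2_on <- FALSE
        }
      }
    }
    samples <- data.frame(minute = minutes, spo2 = as.numeric(spo2),
                          o2_flag = o2_flag, source = "continuous",
                          stringsAsFactors = FALSE)
    # manual room-air entries during qualifying oxygen-off epochs
    if (config$manual_roomair_probability > 0) {
      r <- rle(!o2_flag)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in seq_along(r$lengths)) {
        if (r$values[k] && r$lengths[k] >= 5L &&
            stats::runif(1) < config$manual_roomair_probability) {
          at <- if (r$lengths[k] > 1)
            sample(starts[k]:ends[k], 1) else starts[k]
          samples <- rbind(samples, data.frame(
            minute = at - 1L, spo2 = as.numeric(spo2[at]), o2_flag = FALSE,
            source = "manual_room_air", stringsAsFactors = FALSE))
        }
      }
    }
    list(stream = oximetry_stream(patient_id, samples, total),
         events = events)
  })
}

#' Generate a full synthetic cohort with ground truth
#'
#' Produces one oximetry stream and one patient record per patient. Binary
#' covariates are drawn at the configured prevalences; the OSA-risk stratum
#' drives the desaturation event rate; the early-PRC outcome is drawn from
#' the configured logistic model on the patient's exposure phenotypes
#' (nadir desaturation, oxygen-duration quartile) and covariates; charges
#' are log-normal with quartile-specific parameters. The generating truth
#' (latent events, linear predictors, coefficient map) is returned
#' separately and is never consumed by the analysis modules.
#'
#' @param config A [sim_config()].
#' @return List with `oximetry` (long-format data.frame), `patients`
#'   (one row per patient) and `truth`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  ids <- sprintf("P%06d", seq_len(config$n_patients))
  regions <- c("head", "neck", "intrathoracic", "spine", "upper_abdomen",
               "lower_abdomen", "perineum", "knee", "lower_leg", "shoulder",
               "forearm_hand", "radiological")
  region_probs <- c(0.12, 0.08, 0.03, 0.04, 0.10, 0.15, 0.14, 0.06, 0.05,
                    0.09, 0.05, 0.09)
  region_probs <- region_probs / sum(region_probs)
  high_risk_regions <- c("intrathoracic", "spine", "upper_abdomen",
                         "lower_abdomen", "radiological")
  cov_names <- names(config$covariate_prevalences)
  per_patient <- lapply(ids, function(id) {
    sub_seed <- stable_hash(id, config$seed)
    demo <- with_seed(sub_seed + 1L, {
      sex <- sample(c("male", "female"), 1)
      height <- round(stats::rnorm(1, if (sex == "male") 175 else 162, 7), 1)
      list(
        sex = sex, height = height,
        age = round(min(95, max(18, stats::rnorm(1, 55, 16)))),
        weight = round(max(40, stats::rnorm(1, 85, 20)), 1),
        psap = sample(names(config$psap_probs), 1, prob = config$psap_probs),
        covs = stats::rbinom(length(cov_names), 1,
                             config$covariate_prevalences),
        admission = sample(c("outpatient", "same_day", "inpatient"), 1,
                           prob = c(0.51, 0.36, 0.13)),
        anesthesia_duration = round(stats::rlnorm(1, log(150), 0.5)),
        region = sample(regions, 1, prob = region_probs),
        nmba_agent = sample(c("none", "cisatracurium", "rocuronium",
                              "vecuronium"), 1,
                            prob = c(0.39, 0.06, 0.05, 0.50)),
        stay = if (stats::runif(1) < config$short_stay_prob)
          sample(config$short_stay_range[1]:config$short_stay_range[2], 1)
          else config$pacu_duration_min
      )
    })
    gen <- generate_stream(demo$psap, config, sub_seed, patient_id = id,
                           stay_min = demo$stay)
    list(id = id, demo = demo, gen = gen)
  })

  oximetry <- do.call(rbind, lapply(per_patient, function(p) {
    cbind(patient_id = p$id, p$gen$stream$samples[
      c("minute", "spo2", "o2_flag", "source")])
  }))
  rownames(oximetry) <- NULL

  coefs <- config$outcome_coefficients
  rows <- lapply(per_patient, function(p) {
    s <- p$gen$stream
    nad <- nadir_spo2(s)
    o2 <- oxygen_exposure(s)
    nadir_low <- as.integer(!is.na(nad) && nad < config$truth_nadir_cut)
    o2q <- findInterval(o2$o2_fraction, c(0.25, 0.50, 0.75)) + 1L
    covs <- stats::setNames(as.list(p$demo$covs), cov_names)
    lp <- coefs[["intercept"]]
    for (term in setdiff(names(coefs), "intercept")) {
      xval <- switch(term,
                     nadir_low = nadir_low,
                     o2_quartile = o2q - 1L,
                     covs[[term]])
      lp <- lp + coefs[[term]] * xval
    }
    out <- with_seed(stable_hash(p$id, config$seed) + 2L, {
      early_prc <- stats::rbinom(1, 1, stats::plogis(lp))
      vent <- stats::rbinom(1, 1, stats::plogis(-4.5 + 0.5 * (o2q - 1) +
                                                  1.0 * nadir_low))
      total_ch <- stats::rlnorm(1, config$charge_meanlog[o2q],
                                config$charge_sdlog[o2q])
      list(early_prc = early_prc, vent = vent, total_ch = total_ch,
           dos_frac = stats::runif(1, 0.6, 0.9),
           surg_frac = stats::runif(1, 0.3, 0.6),
           resp_ch = if (vent == 1) stats::rlnorm(1, log(400), 0.8)
                     else if (stats::rbinom(1, 1, 0.2) == 1)
                       stats::rlnorm(1, log(120), 0.8) else 0,
           los = stats::rnbinom(1, size = 1,
                                mu = 0.7 + 0.3 * (o2q - 1) + early_prc),
           mac_frac = stats::runif(1, 0.2, 0.9),
           nmba_dose = stats::rlnorm(1, log(8), 0.6),
           morphine_eq = stats::rlnorm(1, log(12), 0.7))
    })
    rec <- data.frame(
      patient_id = p$id, age = p$demo$age, sex = p$demo$sex,
      height_cm = p$demo$height, weight_kg = p$demo$weight,
      psap = p$demo$psap, admission = p$demo$admission,
      anesthesia_duration_min = p$demo$anesthesia_duration,
      mac_minutes = round(p$demo$anesthesia_duration * out$mac_frac),
      body_region = p$demo$region,
      high_risk_surgery = as.integer(p$demo$region %in% high_risk_regions),
      nmba_agent = p$demo$nmba_agent,
      nmba_dose_mg = if (p$demo$nmba_agent == "none") 0
                     else round(out$nmba_dose, 2),
      morphine_eq_mg = round(out$morphine_eq, 2),
      pacu_duration_min = p$demo$stay,
      early_prc = out$early_prc,
      vent_support = out$vent,
      reintubation = out$early_prc,
      los_days = out$los,
      total_charges = round(out$total_ch, 2),
      day_of_surgery_charges = round(out$total_ch * out$dos_frac, 2),
      surgery_charges = round(out$total_ch * out$surg_frac, 2),
      respiratory_charges = round(out$resp_ch, 2),
      stringsAsFactors = FALSE)
    for (nm in cov_names) rec[[nm]] <- covs[[nm]]
    list(record = rec,
         truth = list(patient_id = p$id, events = p$gen$events,
                      nadir_low = nadir_low, o2_quartile = o2q,
                      linear_predictor = unname(lp)))
  })

  patients <- do.call(rbind, lapply(rows, `[[`, "record"))
  rownames(patients) <- NULL
  truth <- list(seed = config$seed,
                coefficients = as.list(coefs),
                patients = lapply(rows, `[[`, "truth"))
  list(oximetry = oximetry, patients = patients, truth = truth)
}

#' Simulate a tabular outcome cohort with known coefficients
#'
#' A stream-free companion to [generate_cohort()] for validating the
#' modeling stack: binary covariates at configured prevalences, a binary
#' exposure drawn either marginally or from a logistic model on the
#' covariates (which plants genuine confounding), and the outcome drawn
#' from a logistic model with known log-odds. Because the generating
#' coefficients are known exactly, bias, confidence-interval coverage and
#' covariate-selection behaviour can be measured directly.
#'
#' @param n Number of patients.
#' @param outcome_coefficients Named log-odds including `intercept`;
#'   terms may reference `exposure` or any covariate.
#' @param covariate_prevalences Named covariate prevalences.
#' @param exposure_model Either a single probability (marginal exposure
#'   prevalence) or a named log-odds vector including `intercept` for
#'   P(exposure | covariates).
#' @param seed Integer seed.
#' @return Data.frame with covariates, `exposure`, `outcome`; the generating
#'   coefficients are attached as attribute `"truth"`.
#' @export
simulate_outcome_cohort <- function(n, outcome_coefficients,
                                    covariate_prevalences,
                                    exposure_model = 0.15, seed = 1L) {
  allowed <- c("intercept", "exposure", names(covariate_prevalences))
  unknown <- setdiff(names(outcome_coefficients), allowed)
  if (length(unknown) > 0) {
    stop("outcome_coefficients reference unknown term(s): ",
         paste(unknown, collapse = ", "))
  }
  with_seed(seed, {
    dat <- as.data.frame(lapply(covariate_prevalences, function(p) {
      stats::rbinom(n, 1, p)
    }))
    if (is.numeric(exposure_model) && length(exposure_model) == 1 &&
        is.null(names(exposure_model))) {
      dat$exposure <- stats::rbinom(n, 1, exposure_model)
    } else {
      lp <- rep(exposure_model[["intercept"]], n)
      for (term in setdiff(names(exposure_model), "intercept")) {
        lp <- lp + exposure_model[[term]] * dat[[term]]
      }
      dat$exposure <- stats::rbinom(n, 1, stats::plogis(lp))
    }
    lp <- rep(outcome_coefficients[["intercept"]], n)
    for (term in setdiff(names(outcome_coefficients), "intercept")) {
      lp <- lp + outcome_coefficients[[term]] * dat[[term]]
    }
    dat$outcome <- stats::rbinom(n, 1, stats::plogis(lp))
    attr(dat, "truth") <- list(outcome_coefficients = outcome_coefficients,
                               exposure_model = exposure_model, seed = seed)
    dat
  })
}

#' Write or read simulation truth as JSON
#'
#' @param truth Truth object from [generate_cohort()].
#' @param path File path.
#' @return `read_truth_json` returns the truth list.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
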