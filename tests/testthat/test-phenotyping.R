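test_that("centile follows the linear-interpolation convention", {
  expect_equal(centile(0:100, 0.10), 10)
  expect_equal(centile(c(3, 1, 2), 0), 1)
  expect_equal(centile(c(3, 1, 2), 1), 3)
  set.seed(7)
  x <- rnorm(10000)
  for (p in c(0.1, 0.25, 0.5, 0.75, 0.9, 0.33)) {
    expect_equal(centile(x, p), oracle_quantile(x, p))
  }
  expect_error(centile(numeric(0), 0.5), "empty")
  expect_error(centile(1:3, 1.2), "\\[0, 1\\]")
})

test_that("ideal body weight follows the Devine formula", {
  expect_equal(ideal_body_weight(180.34, "male"), 75.3, tolerance = 1e-3)
  expect_equal(ideal_body_weight(152.4, "female"), 45.5)
  h <- 171
  expect_equal(ideal_body_weight(h, "male") - ideal_body_weight(h, "female"),
               4.5)
  expect_error(ideal_body_weight(90, "male"), "height")
})

test_that("dose normalization is per ideal-body-kg per anesthesia hour", {
  expect_equal(normalize_nmba_dose(10, 70, 120), 10 / 70 / 2,
               tolerance = 1e-12)
  expect_equal(as.numeric(normalize_nmba_dose(0, 70, 120)), 0)
  bad <- normalize_nmba_dose(10, 0, 120)
  expect_true(is.na(bad))
  expect_equal(attr(bad, "reason"), "nonpositive_denominator")
})

test_that("morphine equivalents convert and normalize consistently across agents", {
  adm <- data.frame(agent = "morphine", dose_mg = 10)
  expect_equal(morphine_equivalents(adm, 70, 60), 10 / 70, tolerance = 1e-12)
  expect_equal(morphine_equivalents(adm[0, ], 70, 60), 0)
  # 100 ug fentanyl at factor 100 equals 10 mg morphine
  fent <- data.frame(agent = "fentanyl", dose_mg = 0.1)
  expect_equal(morphine_equivalents(fent, 70, 60),
               morphine_equivalents(adm, 70, 60))
  expect_error(morphine_equivalents(
    data.frame(agent = "pethidine", dose_mg = 50), 70, 60), "pethidine")
})

test_that("surgical complexity score ranks regions by outcome risk", {
  set.seed(3)
  n <- 4000
  region <- sample(c("knee", "upper_abdomen"), n, replace = TRUE)
  y <- rbinom(n, 1, ifelse(region == "upper_abdomen", 0.05, 0.01))
  recs <- data.frame(body_region = region, early_prc = y)
  sc <- surgical_complexity_score(recs)
  expect_gt(mean(sc$score[region == "upper_abdomen"]),
            mean(sc$score[region == "knee"]))
  # sign check against the empirical log-odds difference
  emp <- function(r) {
    e <- sum(y == 1 & region == r)
    log(e / (sum(region == r) - e))
  }
  expect_equal(sort(unique(round(sc$score, 6))),
               sort(round(c(emp("knee"), emp("upper_abdomen")), 6)))
  # degenerate single region
  expect_warning(sc1 <- surgical_complexity_score(
    data.frame(body_region = "knee", early_prc = rbinom(50, 1, 0.2))),
    "degenerate")
  expect_true(sc1$degenerate)
  expect_true(all(sc1$high_risk == 0))
  # label permutation only relabels
  region2 <- ifelse(region == "knee", "zknee", region)
  sc2 <- surgical_complexity_score(
    data.frame(body_region = region2, early_prc = y))
  expect_equal(sort(unique(round(sc2$score, 8))),
               sort(unique(round(sc$score, 8))))
})

test_that("thresholds sit at the named centiles and ignore patient order", {
  measures <- data.frame(patient_id = sprintf("P%03d", 1:101),
                         median_spo2 = 0:100, minutes_below_level = 0:100,
                         nadir_spo2 = 0:100, o2_fraction = (0:100) / 100,
                         o2_duration_min = 0:100)
  thr <- derive_thresholds(measures)
  expect_equal(thr$nadir_cut, 10)
  expect_equal(thr$median_cut, 10)
  expect_equal(thr$duration_cut, 90)
  expect_equal(thr$o2_quartile_bounds, c(0.25, 0.50, 0.75))
  set.seed(1)
  thr2 <- derive_thresholds(measures[sample(nrow(measures)), ])
  expect_equal(thr2$median_cut, thr$median_cut)
  expect_equal(thr2$o2_quartile_bounds, thr$o2_quartile_bounds)
  # duplicating the cohort leaves cuts unchanged
  thr3 <- derive_thresholds(rbind(measures, measures))
  expect_equal(thr3$nadir_cut, thr$nadir_cut)
  expect_equal(thr3$duration_cut, thr$duration_cut)
})

test_that("exposure dichotomization uses < for depth cuts and >= for duration cuts", {
  thr <- structure(list(median_cut = 94, duration_cut = 18, nadir_cut = 89,
                        o2_quartile_bounds = c(0.25, 0.50, 0.75),
                        n_used = c(median = 3, duration = 3, nadir = 3,
                                   o2 = 3)),
                   class = "population_thresholds")
  measures <- data.frame(
    patient_id = c("A", "B", "C"),
    median_spo2 = c(93, 94, 95),
    minutes_below_level = c(17.9, 18, 19),
    nadir_spo2 = c(88, 89, 90),
    o2_fraction = c(0.10, 0.50, 0.80),
    o2_duration_min = c(12, 60, 96))
  ex <- assign_exposures(measures, thr)
  expect_equal(ex$nadir_low, c(1L, 0L, 0L))
  expect_equal(ex$median_low, c(1L, 0L, 0L))
  expect_equal(ex$duration_high, c(0L, 1L, 1L))
  # fraction 0.50 lands in the third category
  expect_equal(ex$o2_quartile, c(1L, 3L, 4L))
  # minute-bin rendering of the same quartiles at a 120-minute stay
  ex2 <- assign_exposures(measures, thr, o2_mode = "minutes")
  expect_equal(ex2$o2_quartile, c(1L, 2L, 4L))
})

test_that("derived cuts classify the expected population fractions on tie-free data", {
  set.seed(99)
  n <- 2000
  measures <- data.frame(patient_id = sprintf("P%04d", 1:n),
                         median_spo2 = runif(n, 90, 99),
                         minutes_below_level = runif(n, 0, 60),
                         nadir_spo2 = runif(n, 70, 99),
                         o2_fraction = runif(n),
                         o2_duration_min = runif(n, 0, 120))
  thr <- derive_thresholds(measures)
  ex <- assign_exposures(measures, thr)
  expect_equal(sum(ex$nadir_low), 0.10 * n, tolerance = 1 / n)
  expect_equal(sum(ex$median_low), 0.10 * n, tolerance = 1 / n)
  expect_equal(sum(ex$duration_high), 0.10 * n, tolerance = 1 / n)
  expect_equal(unname(table(ex$o2_quartile)), rep(n / 4, 4),
               ignore_attr = TRUE, tolerance = 2 / n)
})

test_that("two-pass phenotype derivation wires the median cut into the duration measure", {
  co <- generate_cohort(sim_config(n_patients = 60, seed = 13))
  ph <- derive_cohort_phenotypes(co$oximetry, records = co$patients,
                                 pacu_durations = stats::setNames(
                                   co$patients$pacu_duration_min,
                                   co$patients$patient_id))
  expect_equal(nrow(ph$measures), 60)
  # duration was recomputed at the derived median cut
  sid <- ph$measures$patient_id[1]
  streams <- as_stream_list(co$oximetry)
  expect_equal(ph$measures$minutes_below_level[1],
               as.numeric(minutes_below_level(streams[[sid]],
                                              ph$thresholds$median_cut)))
  expect_true(all(ph$exposures$o2_quartile %in% 1:4))
})
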