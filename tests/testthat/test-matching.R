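test_that("greedy matching reproduces the hand trace with its tie-break", {
  scores <- c(0.9, 0.5, 0.1, 0.85, 0.45, 0.20, 0.15, 0.05)
  exposed <- c(1, 1, 1, 0, 0, 0, 0, 0)
  m <- nearest_neighbor_match(scores, exposed)
  expect_equal(m$pairs$exposed_id, c(1, 2, 3))
  # 0.1 ties between 0.15 and 0.05 at gap 0.05: lowest control index wins
  expect_equal(m$pairs$control_id, c(4, 5, 7))
  # identical multisets: every exposed matched at zero gap
  m2 <- nearest_neighbor_match(c(0.3, 0.6, 0.3, 0.6), c(1, 1, 0, 0))
  expect_equal(m2$pairs$gap, c(0, 0))
  expect_length(m2$unmatched_exposed, 0)
  # caliper over disjoint ranges leaves everyone unmatched
  m3 <- nearest_neighbor_match(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0),
                               caliper = 0.01)
  expect_equal(nrow(m3$pairs), 0)
  expect_length(m3$unmatched_exposed, 2)
})

test_that("matching equals an exhaustive greedy trace on random small fixtures", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(10:50, 1)
    scores <- round(runif(n), 2)  # ties likely
    exposed <- rbinom(n, 1, 0.4)
    if (sum(exposed) == 0 || sum(exposed) == n) next
    cal <- if (seed %% 3 == 0) 0.05 else NULL
    got <- nearest_neighbor_match(scores, exposed, caliper = cal)
    want <- oracle_greedy_match(scores, exposed, caliper = cal)
    expect_equal(got$pairs$exposed_id, want$exposed, info = paste("seed", seed))
    expect_equal(got$pairs$control_id, want$control, info = paste("seed", seed))
    # without replacement: no control reused
    expect_false(any(duplicated(got$pairs$control_id)))
  }
})

test_that("greedy prefix is stable when a later control is removed", {
  set.seed(5)
  scores <- runif(30)
  exposed <- rep(c(1, 0), 15)
  m <- nearest_neighbor_match(scores, exposed)
  drop_ctl <- m$pairs$control_id[nrow(m$pairs)]
  keep <- setdiff(seq_along(scores), drop_ctl)
  m2 <- nearest_neighbor_match(scores[keep], exposed[keep], ids = keep)
  k <- nrow(m$pairs) - 1
  expect_equal(m2$pairs$exposed_id[1:k], m$pairs$exposed_id[1:k])
  expect_equal(m2$pairs$control_id[1:k], m$pairs$control_id[1:k])
})

test_that("rare-procedure exclusion applies the count floor exactly", {
  recs <- data.frame(patient_id = 1:149,
                     body_region = rep(c("a", "b", "c"), c(49, 50, 50)))
  out <- exclude_rare_procedures(recs, floor = 50)
  expect_false("a" %in% out$records$body_region)
  expect_true(all(c("b", "c") %in% out$records$body_region))
  expect_equal(out$excluded$count, 49)
  expect_equal(nrow(out$records) + sum(out$excluded$count), nrow(recs))
  expect_equal(nrow(exclude_rare_procedures(recs, floor = 0)$records),
               nrow(recs))
  expect_error(exclude_rare_procedures(recs, floor = 1000), "floor")
})

test_that("propensity scores reflect covariate strength and ignore row order", {
  set.seed(6)
  n <- 4000
  d <- data.frame(patient_id = 1:n, conf = rbinom(n, 1, 0.4),
                  junk = rbinom(n, 1, 0.5))
  d$exposure <- rbinom(n, 1, plogis(-1 + 1.5 * d$conf))
  ps <- fit_propensity("exposure", c("conf", "junk"), d)
  expect_true(all(ps$scores > 0 & ps$scores < 1))
  expect_gt(c_statistic(ps$scores, d$exposure)$c_statistic, 0.55)
  ps2 <- fit_propensity("exposure", c("conf", "junk"), d[rev(seq_len(n)), ])
  expect_equal(ps2$scores, rev(ps$scores), tolerance = 1e-10)
  # covariates independent of exposure: scores pile at the prevalence
  d$exposure2 <- rbinom(n, 1, 0.3)
  ps3 <- fit_propensity("exposure2", c("conf", "junk"), d)
  expect_lt(diff(range(ps3$scores)), 0.1)
})

test_that("matching improves balance on a planted confounder", {
  set.seed(7)
  n <- 3000
  d <- data.frame(patient_id = sprintf("P%04d", 1:n),
                  conf = rbinom(n, 1, 0.4),
                  other = rbinom(n, 1, 0.2),
                  stringsAsFactors = FALSE)
  # exposure odds shifted hard by the confounder, with enough controls in
  # the confounded stratum for greedy matching to draw on
  d$exposure <- rbinom(n, 1, plogis(-2.6 + 2.2 * d$conf))
  ps <- fit_propensity("exposure", c("conf", "other"), d)
  m <- nearest_neighbor_match(ps$scores, d$exposure, ids = d$patient_id)
  bal <- balance_table(m, d, c("conf", "other"), "exposure")
  conf_row <- bal[bal$variable == "conf", ]
  expect_gt(conf_row$pre_smd, 0.4)
  expect_lt(abs(conf_row$post_smd), 0.1)
  expect_lt(abs(conf_row$post_smd), abs(conf_row$pre_smd))
})

test_that("standardized mean differences follow their conventions", {
  # matched groups of duplicated patients balance exactly
  x <- c(1, 0, 1, 0, 5, 2, 5, 2)
  g <- c(1, 1, 0, 0, 1, 0, 1, 0)
  expect_equal(standardized_mean_difference(c(1, 0, 1, 0), c(1, 0, 1, 0)), 0)
  expect_equal(standardized_mean_difference(rep(3, 10), rep(c(1, 0), 5)), 0)
  smd <- standardized_mean_difference(x, g)
  expect_equal(standardized_mean_difference(x, 1 - g), -smd)
  # binary convention: difference in proportions over pooled binary SD
  xb <- c(1, 1, 0, 0, 1, 0, 0, 0)
  gb <- c(1, 1, 1, 1, 0, 0, 0, 0)
  p1 <- 0.5; p0 <- 0.25
  expect_equal(standardized_mean_difference(xb, gb),
               (p1 - p0) / sqrt((p1 * (1 - p1) + p0 * (1 - p0)) / 2))
})

test_that("matched outcome comparisons agree with the univariate building blocks", {
  set.seed(8)
  n <- 1200
  d <- data.frame(patient_id = sprintf("P%04d", 1:n),
                  exposure = rep(c(1, 0), n / 2),
                  total_charges = exp(rnorm(n, 9.3 + 0.2 * rep(c(1, 0), n / 2),
                                            0.6)),
                  los_days = rpois(n, 1),
                  reintubation = rbinom(n, 1, 0.02),
                  vent_support = rbinom(n, 1, 0.04),
                  o2_quartile = sample(1:4, n, replace = TRUE),
                  stringsAsFactors = FALSE)
  scores <- runif(n)
  m <- nearest_neighbor_match(scores, d$exposure, ids = d$patient_id)
  res <- matched_outcomes(m, d, "exposure",
                          continuous = c("total_charges", "los_days"),
                          binary = c("reintubation", "vent_support"),
                          o2_quartile = "o2_quartile")
  # charges simulated higher in the exposed stratum
  ch <- res$continuous[res$continuous$outcome == "total_charges", ]
  expect_gt(ch$exposed_median, ch$control_median)
  expect_lt(ch$p_value, 0.01)
  # binary OR equals the Woolf OR on the same 2x2
  ids <- c(m$pairs$exposed_id, m$pairs$control_id)
  sub <- d[d$patient_id %in% ids, ]
  a <- sum(sub$reintubation == 1 & sub$exposure == 1)
  b <- sum(sub$reintubation == 1 & sub$exposure == 0)
  cc <- sum(sub$reintubation == 0 & sub$exposure == 1)
  dd <- sum(sub$reintubation == 0 & sub$exposure == 0)
  want <- odds_ratio_woolf(a, b, cc, dd)
  got <- res$binary[res$binary$outcome == "reintubation", ]
  expect_equal(got$or, want$or)
  expect_equal(got$ci_low, want$ci_low)
  # quartile charge table covers all four quartiles with valid counts
  q <- res$charges_by_quartile$unmatched
  expect_equal(q$quartile, 1:4)
  expect_equal(sum(q$total_n), n)
})
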