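sim_basic <- function(n = 20000, seed = 1, exposure_beta = 0.7) {
  simulate_outcome_cohort(
    n,
    c(intercept = -4.2, exposure = exposure_beta, copd = 1.0,
      renal_disease = 0.9, noise = 0),
    c(copd = 0.06, renal_disease = 0.09, noise = 0.30),
    exposure_model = 0.15, seed = seed)
}

test_that("a covariate independent of the outcome gets a null adjusted OR", {
  dat <- sim_basic(seed = 3)
  m <- fit_logistic("outcome", c("exposure", "copd", "noise"), dat)
  row <- m$coef_table[m$coef_table$term == "noise", ]
  expect_lt(abs(log(row$aor)), 0.2)
  expect_true(row$ci_low < 1 && 1 < row$ci_high)
  # AOR/CI identities from the estimates
  expect_equal(m$coef_table$aor, exp(m$coef_table$estimate))
  expect_equal(m$coef_table$ci_low,
               exp(m$coef_table$estimate -
                     qnorm(0.975) * m$coef_table$se))
})

test_that("perfect separation is detected and named", {
  d <- data.frame(y = c(rep(0, 30), rep(1, 30)),
                  sep = c(rep(0, 30), rep(1, 30)),
                  x = rnorm(60))
  expect_error(fit_logistic("y", c("sep", "x"), d), "sep")
  expect_error(fit_logistic("y", "x", data.frame(y = rep(1, 20),
                                                 x = rnorm(20))),
               "both classes")
})

test_that("fit is invariant to row order and indicator recoding flips the sign", {
  dat <- sim_basic(n = 5000, seed = 4)
  m1 <- fit_logistic("outcome", c("exposure", "copd"), dat,
                     diagnostics = FALSE)
  set.seed(1)
  m2 <- fit_logistic("outcome", c("exposure", "copd"),
                     dat[sample(nrow(dat)), ], diagnostics = FALSE)
  expect_equal(m1$coef_table$estimate, m2$coef_table$estimate,
               tolerance = 1e-8)
  flipped <- dat
  flipped$exposure <- 1 - flipped$exposure
  m3 <- fit_logistic("outcome", c("exposure", "copd"), flipped,
                     diagnostics = FALSE)
  expect_equal(m3$coef_table$estimate[m3$coef_table$term == "exposure"],
               -m1$coef_table$estimate[m1$coef_table$term == "exposure"],
               tolerance = 1e-6)
})

test_that("linearity of logits separates log-linear from U-shaped level effects", {
  # counts with event odds 0.01, 0.02, 0.04: equal log2 steps -> ordinal
  lvl <- rep(c(0, 1, 2), times = c(1010, 1020, 1040))
  y <- c(rep(c(1, 0), c(10, 1000)), rep(c(1, 0), c(20, 1000)),
         rep(c(1, 0), c(40, 1000)))
  res <- linearity_of_logits(lvl, y)
  expect_equal(res$decision, "ordinal")
  expect_equal(unname(res$steps), rep(log(2), 2), tolerance = 1e-12)
  # U-shaped odds -> indicator coding
  lvl2 <- rep(c(0, 1, 2), times = c(1040, 1010, 1040))
  yu <- c(rep(c(1, 0), c(40, 1000)), rep(c(1, 0), c(10, 1000)),
          rep(c(1, 0), c(40, 1000)))
  expect_equal(linearity_of_logits(lvl2, yu)$decision, "indicator")
  # binary variables pass through
  expect_equal(linearity_of_logits(rep(0:1, 50), rbinom(100, 1, 0.3))$decision,
               "ordinal")
  # zero-event level triggers the continuity correction flag
  lvl3 <- rep(c(0, 1, 2), times = c(1000, 1020, 1040))
  yz <- c(rep(0, 1000), rep(c(1, 0), c(20, 1000)),
          rep(c(1, 0), c(40, 1000)))
  expect_true(linearity_of_logits(lvl3, yz)$corrected)
})

test_that("change-in-estimate selection keeps confounders and sheds noise", {
  # planted confounder: drives both exposure assignment and outcome
  dat <- simulate_outcome_cohort(
    20000,
    c(intercept = -4.5, exposure = 0.7, conf = 1.5, noise = 0),
    c(conf = 0.35, noise = 0.30),
    exposure_model = c(intercept = -2.2, conf = 1.5), seed = 42)
  sel <- change_in_estimate_selection("outcome", "exposure",
                                      c("conf", "noise"), dat,
                                      diagnostics = FALSE)
  expect_true("conf" %in% sel$retained_candidates)
  expect_true("noise" %in% sel$dropped_candidates)
  led <- sel$ledger
  expect_equal(led$action[led$term == "noise"], "dropped")
  expect_equal(led$action[led$term == "conf"], "retained")
  # refit-both-models oracle for the recorded deltas
  beta_of <- function(terms) {
    f <- glm(reformulate(terms, "outcome"), binomial(), dat)
    unname(coef(f)["exposure"])
  }
  d_noise <- abs(beta_of(c("exposure", "conf", "noise")) -
                   beta_of(c("exposure", "conf")))
  d_conf <- abs(beta_of(c("exposure", "conf")) - beta_of("exposure"))
  expect_equal(led$delta[led$term == "noise"], d_noise, tolerance = 1e-6)
  expect_equal(led$delta[led$term == "conf"], d_conf, tolerance = 1e-6)
  expect_gt(d_conf, 0.10)
  expect_lt(d_noise, 0.10)
  # empty candidate list: exposure-only model
  sel0 <- change_in_estimate_selection("outcome", "exposure", character(0),
                                       dat, diagnostics = FALSE)
  expect_equal(sel0$coef_table$term, c("(Intercept)", "exposure"))
  # ledger replay: refitting the final term set reproduces the estimates
  replay <- fit_logistic("outcome", c("exposure", sel$retained_candidates),
                         dat, diagnostics = FALSE)
  expect_equal(replay$coef_table$estimate, sel$coef_table$estimate,
               tolerance = 1e-10)
})

test_that("interaction matrix transposes under stratum relabeling and flags empty cells", {
  dat <- simulate_outcome_cohort(
    8000, c(intercept = -3, exposure = 0.5, strat = 0.4),
    c(strat = 0.4), exposure_model = 0.3, seed = 5)
  ia <- interaction_analysis("outcome", "exposure", "strat", data = dat)
  expect_false(ia$degenerate)
  expect_equal(dim(ia$aor_matrix), c(2, 2))
  expect_equal(ia$aor_matrix[1, 1], 1)
  flip <- dat
  flip$strat <- 1 - flip$strat
  iaf <- interaction_analysis("outcome", "exposure", "strat", data = flip)
  # relabeling the stratum swaps the columns up to the reference cell
  expect_equal(ia$aor_matrix[2, 2] / ia$aor_matrix[1, 2],
               iaf$aor_matrix[2, 1] / iaf$aor_matrix[1, 1],
               tolerance = 1e-6)
  deg <- dat[dat$exposure == 0 | dat$strat == 0, ]
  expect_true(interaction_analysis("outcome", "exposure", "strat",
                                   data = deg)$degenerate)
})

test_that("stratified models run per stratum and isolate failures", {
  dat <- sim_basic(n = 30000, seed = 6)
  set.seed(7)
  dat$strat <- rbinom(nrow(dat), 1, 0.5)  # independent of everything
  res <- stratified_models("outcome", "exposure", c("copd", "noise"),
                           dat, "strat", diagnostics = FALSE)
  expect_length(res, 2)
  aors <- vapply(res, function(m) {
    m$coef_table$aor[m$coef_table$term == "exposure"]
  }, numeric(1))
  expect_lt(abs(log(aors[1] / aors[2])), 0.6)
  for (m in res) {
    expect_setequal(c(m$retained_candidates, m$dropped_candidates,
                      m$ledger$term[m$ledger$action == "retained"]),
                    union(c("copd", "noise"), m$retained_candidates))
  }
  # a stratum without events fails alone
  dat2 <- dat
  dat2$outcome[dat2$strat == 1] <- 0
  res2 <- stratified_models("outcome", "exposure", c("copd", "noise"),
                            dat2, "strat", diagnostics = FALSE)
  expect_s3_class(res2[["strat=0"]], "prc_model")
  expect_s3_class(res2[["strat=1"]], "condition")
})

test_that("diagnostics match brute-force oracles on small fixtures", {
  # full score separation
  cs <- c_statistic(c(0.9, 0.8, 0.7, 0.4), c(1, 1, 0, 0))
  expect_equal(cs$c_statistic, 1.0)
  # scores independent of outcome hover near 0.5
  set.seed(8)
  sc <- runif(20000)
  y <- rbinom(20000, 1, 0.3)
  expect_lt(abs(c_statistic(sc, y)$c_statistic - 0.5), 0.02)
  # n = 20 all-pairs oracle, with ties
  set.seed(9)
  sc20 <- round(runif(20), 1)
  y20 <- rbinom(20, 1, 0.4)
  expect_equal(c_statistic(sc20, y20)$c_statistic,
               oracle_concordance(sc20, y20))
  # VIF equals 1/(1-R^2) from independently fitted auxiliary regressions
  set.seed(10)
  X <- cbind(x1 = rnorm(200), x2 = rnorm(200))
  X <- cbind(X, x3 = X[, 1] * 0.8 + rnorm(200, sd = 0.5))
  v <- vif_from_design(X)
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-10)
  }
  # cross-check against car::vif (weighted-design variant, so agreement is
  # close but not exact)
  skip_if_not_installed("car")
  d <- data.frame(y = rbinom(200, 1, 0.4), X)
  fit <- glm(y ~ x1 + x2 + x3, binomial(), d)
  expect_equal(unname(vif_from_design(model.matrix(fit)[, -1])),
               unname(car::vif(fit)), tolerance = 0.02)
})

test_that("c-statistic agrees with pROC on a fitted model", {
  skip_if_not_installed("pROC")
  dat <- sim_basic(n = 4000, seed = 12)
  m <- fit_logistic("outcome", c("exposure", "copd"), dat)
  auc <- as.numeric(pROC::auc(pROC::roc(dat$outcome, fitted(m$fit),
                                        quiet = TRUE, direction = "<")))
  expect_equal(m$diagnostics$c_statistic, auc, tolerance = 1e-10)
})

test_that("Hosmer-Lemeshow equals hand-grouped deciles on a spread fixture", {
  set.seed(11)
  p <- seq(0.05, 0.95, length.out = 40)
  y <- rbinom(40, 1, p)
  got <- hosmer_lemeshow(p, y, groups = 10)
  # independent grouping: sorted risk in consecutive chunks of 4
  ord <- order(p)
  stat <- 0
  for (g in 1:10) {
    idx <- ord[((g - 1) * 4 + 1):(g * 4)]
    e1 <- sum(p[idx]); o1 <- sum(y[idx])
    e0 <- 4 - e1; o0 <- 4 - o1
    stat <- stat + (o1 - e1)^2 / e1 + (o0 - e0)^2 / e0
  }
  expect_equal(got$statistic, stat, tolerance = 1e-10)
  expect_equal(got$df, 8)
  expect_warning(hosmer_lemeshow(rep(c(0.2, 0.4), 50), rbinom(100, 1, 0.3)),
                 "collapsed")
})

test_that("condition indices and the omnibus test behave as defined", {
  set.seed(13)
  X <- cbind(1, matrix(rnorm(300), 100, 3))
  ci <- condition_indices(X)
  expect_equal(ci[1], 1)
  expect_true(all(diff(ci) >= 0))
  # collinear design produces a large index
  Xc <- cbind(X, X[, 2] + rnorm(100, sd = 1e-4))
  expect_gt(max(condition_indices(Xc)), 30)
  dat <- sim_basic(n = 5000, seed = 14)
  m <- fit_logistic("outcome", c("exposure", "copd"), dat)
  om <- m$diagnostics$omnibus
  expect_equal(om$statistic, m$fit$null.deviance - m$fit$deviance)
  expect_equal(om$df, 2)
})
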