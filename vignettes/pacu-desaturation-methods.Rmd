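---
title: "Methods: PACU desaturation phenotypes and early respiratory complications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PACU desaturation phenotypes and early respiratory complications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacudesat)
```

## The scientific setting

Patients recovering from anesthesia are monitored with per-minute pulse
oximetry in the post-anesthesia care unit (PACU). Desaturation there is
common but heavily managed — alarms wake patients, nurses start
supplemental oxygen — so most recorded values sit in the normal range and a
single threshold crossing is a poor phenotype. The strategy implemented
here converts each patient's stream into a small set of interpretable
measures capturing *depth*, *duration* and *clinical response*, then
dichotomizes each against the **population spread** of the measure rather
than a fixed physiological constant. The binary outcome of interest, early
postoperative respiratory complication (early PRC), is reintubation or new
intubation within three days of anesthesia end; it is consumed as a data
field, not re-derived from charts.

## Stream-level measures

For a stream of integer SpO2 samples at minutes 0, 1, 2, … (0-based,
half-open intervals throughout):

* **Censoring and artifacts.** Central-tendency and duration measures use
  the first 120 minutes only, so long stays do not dominate the population
  spread; nadir and oxygen exposure use the full stay, because the worst
  desaturation and the total oxygen requirement are stay-level facts.
  Values below 60% are treated as artifact (pulse oximetry is not validated
  below that, and dislodged sensors read low) and become missing rather
  than signal.
* **Median SpO2** is the median of all 5-minute sliding-window medians
  (advanced 1 minute at a time, windows fully inside the censored span). A
  window yields a median only when at least ceiling(5/2) = 3 of its minutes
  carry valid samples; this prevents one stray value from acting as a
  "median". Even-length medians use the mean of the two central order
  statistics.
* **Desaturation duration** is 60 × #{valid minutes below the level} /
  #{valid minutes}, i.e. minutes per monitored hour. The level is the
  *population* median cutoff (the 10th centile of per-patient medians), not
  each patient's own median — the operational definition "minutes below
  94%" in the motivating work fixes a single cohort-level threshold. This
  makes the derivation order-sensitive: medians must be summarized across
  the cohort before any duration can be computed, which
  `derive_cohort_phenotypes()` orchestrates as a two-pass flow.
* **Nadir SpO2** is the minimum over (i) all valid continuous samples
  through discharge and (ii) manual room-air entries charted by the nurse
  inside an oxygen-off epoch of at least five minutes. Whether the nadir
  search should stop at 120 minutes is genuinely ambiguous in the source
  definitions ("through to PACU discharge" vs the general 120-minute
  censoring); the full-stay reading is the default and a `censor` flag
  provides the alternative. The five-minute room-air qualification is
  operationalized as a run of consecutive continuous minutes with the
  oxygen flag off containing the entry's minute; an unobserved minute
  breaks the run, since the oxygen state there is unknown.
* **Oxygen exposure** counts flagged minutes over the full stay and divides
  by the stay length.

## Population thresholds and exposures

All centiles use linear interpolation of order statistics at position
`1 + p(n - 1)` (the common type-7 rule); the convention is stated because
the choice is not standardized across software and the cuts land directly
on patient classification. Boundary conventions follow the phrasing of the
clinical definitions: strict `<` for the nadir and median cuts ("nadir
desaturation <89%"), `>=` for the duration cut ("cumulative time >= 18
minutes per hour") and for every 75th-centile high-dose flag ("equal to or
greater than"). Oxygen-duration categories are quartiles of the oxygen
fraction by default; at the standard 120-minute censored stay these
correspond to the minute bins <30, 31–60, 61–90, >90, and a `"minutes"`
mode applies those fixed bins instead, because the source description
supports either reading.

Drug exposures are normalized before cutting: neuromuscular blocker and
opioid doses are divided by Devine ideal body weight (50 kg male / 45.5 kg
female + 2.3 kg per inch over 60) and by anesthesia hours, giving
mg·kg⁻¹·hr⁻¹. Opioid agents are first converted to morphine equivalents
with an editable table (defaults: morphine 1, hydromorphone 6.67, fentanyl
100 per mg) — these factors are conventional equianalgesic assumptions, not
estimates. The surgical complexity score is the fitted linear predictor of
a logistic regression of the outcome on procedure body-region indicators,
dichotomized at its 75th centile; with a single region the score is
degenerate and flagged rather than cut.

## Univariate layer

2x2 odds ratios use the Woolf interval. When any cell is zero the
Haldane–Anscombe correction (0.5 added to all four cells) is applied and
flagged; the source tables are silent on zero cells, so the most common
convention was chosen. Pearson chi-square is used without continuity
correction (configurable), matching the named test. Variables with more
than 5% missingness are flagged and audited with an outcome-vs-missingness
odds ratio, the check that missingness is not outcome-informative.

## Modeling layer

Logistic models are fitted by maximum likelihood (IRLS, relative deviance
tolerance 1e-8, at most 100 iterations). Plain ML is used deliberately —
no Firth or other rare-event correction — to mirror standard practice in
this literature; any coefficient exceeding 15 in magnitude is reported as
quasi-separation with the offending term named, because at that point the
MLE is effectively unbounded and its Wald statistics meaningless.

**Change-in-estimate selection.** Starting from the full model, the
removable covariate with the largest Wald p is removed and the change in
the primary exposure's estimate measured as `|ln(AOR_full / AOR_reduced)|`
(absolute value; the direction of the shift is not informative for
confounding). A change above 0.10 restores the covariate and, by default,
stops the whole procedure — the rule "continue until the first variable
produces a change >10%". Two readings of the reference model are defensible
and both are provided: the default compares against the *current* model
(sequential), a flag compares every removal against the original full
model. Ties in Wald p break by candidate-list order; for factor terms the
term's p is the smallest of its contrasts' p-values. Every step is recorded
in a ledger (term, p, delta, action) so the final model can be replayed.

**Linearity of logits.** Ordinal candidates keep ordinal coding when their
per-level empirical logit steps are monotone and near-constant (maximum
deviation of a step from the mean step at most 0.15 on the log-odds scale,
configurable); otherwise they are recoded as indicators. Zero-event levels
get a 0.5 continuity correction and a flag. The 0.15 band is a pragmatic
default: it tolerates sampling noise in rare-event logits while still
catching U-shapes and threshold effects.

**Interaction and stratification.** The exposure-by-surgical-risk decision
uses a product term; cell adjusted odds ratios are reported against the
joint reference cell, and stratified selection pipelines run per stratum
when the product-term Wald p falls below 0.05 (the source says "evidence of
significant interaction" without a number; 0.05 is the conventional
choice). Which pair of variables interacts is a parameter, not hard-coded,
because the source is internally inconsistent about whether the OSA-risk
score or the nadir phenotype was the interacting exposure.

**Diagnostics.** The c-statistic is the concordance of fitted risks over
all case-control pairs (ties half) with the Hanley–McNeil standard error;
Hosmer–Lemeshow groups deciles of risk with df = groups − 2 (tied risks
collapse groups, with a warning); VIFs come from ordinary auxiliary
regressions on the design matrix (`1/(1 − R²)`), which is the textbook
definition — the weighted-design variant some packages report differs
slightly and is used only as a cross-check in the tests; condition indices
are ratios of singular values of the column-equilibrated design including
the intercept; the omnibus test is the likelihood-ratio chi-square against
the intercept-only model.

## Matching layer

The matched exposure is oxygen-therapy duration above the lowest quartile.
Procedure categories with fewer than 50 patients are excluded first so the
procedure indicators in the propensity model are estimable. The propensity
model may contain pre- and intra-operative variables only — post-PACU
variables are consequences of the exposure and would over-control.
Matching is greedy 1:1 nearest-neighbor without replacement, walking the
exposed group in descending score order (common practice; a seeded random
order is available for sensitivity analyses), with ties broken by lowest
control index and an optional caliper. Greedy order and tie-break are fully
deterministic, which the tests exploit by comparing against an exhaustive
trace. Balance is verified with standardized mean differences (difference
in means over the pooled SD; binary variables use the pooled binomial SD)
and the univariate tests; matched outcomes are compared with
independent-sample tests, matching the presentation style of the source
tables (a paired McNemar analysis would be the stricter alternative and is
a documented deviation if enabled).

## The synthetic cohort generator

No anesthesia-information-system dataset of this kind is publicly
deposited, so the package generates its own cohorts with known truth.

* **SpO2 mechanism.** Each patient has a baseline (default 97%) with
  per-minute Gaussian noise (sd 1%). Desaturation events arrive as a
  homogeneous Poisson process at a rate set by the patient's OSA-risk
  stratum (defaults 0.5 / 1.5 / 3 events per hour for low / moderate /
  high risk), with exponential durations (mean 3 min) and Gaussian depths
  (mean 10%, sd 4%) — the simplest process family consistent with
  "episodic desaturation". Displayed values are clipped to [60, 100] and
  rounded to integers, as monitors report.
* **Nurse response.** When the displayed value stays below the alarm
  threshold (90%) for the nurse-response delay (2 min), oxygen turns on,
  adds the uplift (5%), and stays on until the event has ended plus a
  washout (10 min). Most patients additionally arrive on oxygen
  (probability 0.85, exponential mean 40 min), which is routine clinical
  practice and gives the oxygen-duration fraction a continuous spread
  rather than a pile of zeros. Oxygen-off epochs of five or more minutes
  receive a charted manual room-air entry with probability 0.3.
* **Covariates, outcome, charges.** Binary covariates are Bernoulli at
  prevalences defaulted to the frequencies typical of a large surgical
  cohort (COPD 6%, renal disease 9%, sepsis 1%, …). The outcome is drawn
  from a logistic model with known coefficients on the patient's true
  phenotype flags and covariates; the default intercept puts incidence
  near 0.3%, the observed rarity of early PRC. Total charges are
  log-normal with oxygen-duration-stratum parameters (medians rising from
  about $10.2k to $13.2k across strata, log-sd 0.56–0.79, consistent with
  heavily right-skewed hospital charge data); length of stay is negative
  binomial.
* **Determinism.** One master seed spawns per-patient substreams via a
  stable hash of the patient id, so enlarging a cohort never reshuffles
  existing patients; `(seed, config)` fully determines every output, and
  the truth object (latent events, linear predictors, generating
  coefficients) is emitted alongside the data but never consumed by the
  analysis modules.

What the generator does *not* emulate: second-resolution apnea dynamics,
physiologic gas exchange, circadian worsening over postoperative nights,
informative missingness, or coding error in covariates. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers known
structure under its own assumptions — not that those assumptions hold in
any particular hospital's data.

A stream-free companion, `simulate_outcome_cohort()`, draws the tabular
part alone (covariates, exposure — marginally or from a logistic model on
covariates to plant genuine confounding — and outcome). The
parameter-recovery, selection-correctness and interaction size/power
studies use it with 100 replicates of 20,000 patients each: those studies
validate the modeling stack, for which simulating two million minute-level
streams would add nothing but runtime. The stream mechanism is exercised
separately by the metric oracles and the end-to-end pipeline runs at
moderate cohort sizes (hundreds to thousands of patients).

## Numerical and degenerate-input choices

* Quantiles: type-7 everywhere, recorded in the run report.
* Even-length medians: mean of the central order statistics.
* Empty or all-artifact streams: measures come back missing with a reason
  code (`insufficient_data`, `artifact`) rather than erroring; cleaning is
  total.
* Zero 2x2 cells: Haldane–Anscombe 0.5, flagged; an empty margin yields an
  undefined OR, not an error.
* Matching with exhausted controls: exposed patients go unmatched and are
  reported, not fatal.
* Constant balance variables: SMD 0 by convention.
* The generator's event-rate monotonicity ("more events, more time below
  threshold") holds in distribution and is tested as a comparison of means
  across replicates; the implementation does not couple random draws
  across configurations, so a per-draw guarantee is not claimed.

## Known limitations

* The change-in-estimate procedure inherits the instability of any
  stepwise method at very low event counts; the quasi-separation guard
  turns silent failures into errors but cannot rescue the fit (a Firth
  option would, at the cost of departing from the reference methodology).
* Population thresholds are dataset-specific by design: the 94% / 18
  min·hr⁻¹ / 89% cuts reported for the motivating cohort will not
  reproduce on synthetic data and are not targets.
* The oxygen-duration quartile bins assume a 120-minute stay when rendered
  in minutes; shorter stays are handled in fraction mode only.
* Greedy matching is order-dependent by construction; optimal matching is
  out of scope.
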