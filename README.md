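# pacudesat

Phenotyping post-anesthesia care unit (PACU) pulse-oximetry desaturation and
modeling its association with early postoperative respiratory complications
(PRC) and hospital resource use.

## The problem

Continuous SpO2 is recorded every minute while a patient recovers in the
PACU, but there is no accepted way to turn those noisy, heavily-managed
streams into respiratory risk phenotypes: desaturations are interrupted by
alarms and nurse-administered oxygen, so single threshold crossings carry
little information. `pacudesat` implements a population-centile approach for
epidemiologists and perioperative researchers working with anesthesia
information systems:

1. **Stream metrics.** For each patient, four measures over the stay
   (censored at 120 min for central tendency and duration; full stay for
   nadir and oxygen exposure, with a 60% artifact floor):
   - median SpO2 = median of all 5-minute sliding-window medians,
   - desaturation duration = 60 x #{min: SpO2 < c} / #{monitored min}
     (minutes per monitored hour below the population median cutoff c),
   - nadir SpO2 = min over continuous samples and qualifying manual
     room-air entries (charted inside an oxygen-off epoch of >= 5 min),
   - oxygen therapy duration and its fraction of the PACU stay.
2. **Population thresholds.** Type-7 centiles over the cohort dichotomize
   the measures: 10th centile of medians and nadirs (`<` cut), 90th centile
   of durations (`>=` cut), quartiles of the oxygen fraction; 75th-centile
   cuts flag high drug exposures (doses normalized per Devine ideal body
   weight per anesthesia hour).
3. **Univariate statistics.** 2x2 odds ratios with Woolf confidence
   intervals, `exp(ln OR ± z·sqrt(1/a + 1/b + 1/c + 1/d))`, Pearson
   chi-square, t / Mann-Whitney comparisons, and a missingness audit with a
   5% review threshold.
4. **Change-in-estimate modeling.** Logistic regression of early PRC with
   the desaturation phenotype as the fixed primary exposure; backward
   selection removes the covariate with the largest Wald p unless
   `|ln(AOR_full / AOR_reduced)| > 0.10`, stopping at the first retained
   confounder. Linearity-of-logits checks choose ordinal vs indicator
   coding; diagnostics report the c-statistic (Hanley-McNeil SE),
   Hosmer-Lemeshow test, variance inflation factors, condition indices and
   the omnibus likelihood-ratio test. Interaction with surgical risk is
   tested with a product term and drives stratified models.
5. **Propensity matching.** Logistic propensity for prolonged oxygen
   therapy (above the lowest duration quartile) on pre/intra-operative
   covariates, greedy 1:1 nearest-neighbor matching without replacement in
   descending score order, balance verification via standardized mean
   differences, and matched comparisons of charges, length of stay and
   ventilatory support.

Because no patient-level PACU dataset of this kind is publicly deposited,
the package ships a synthetic cohort generator (`sim_config()`,
`generate_cohort()`) that emulates per-minute SpO2 streams with episodic
desaturation events, a nurse oxygen-response loop, configurable covariate
prevalences, a logistic outcome model with known coefficients, and skewed
charge data — so every stage of the pipeline can be validated against known
ground truth.

## Worked example

```r
library(pacudesat)

cfg <- sim_config(n_patients = 1000, seed = 7,
                  outcome_coefficients = c(intercept = -3.2, nadir_low = 0.7,
                                           o2_quartile = 0.35, copd = 1.0))
cohort <- generate_cohort(cfg)
durations <- setNames(cohort$patients$pacu_duration_min,
                      cohort$patients$patient_id)
ph <- derive_cohort_phenotypes(cohort$oximetry, records = cohort$patients,
                               pacu_durations = durations)
ph$thresholds
#> <population_thresholds>
#>   median SpO2 cut (10th centile): 97.00% (n=1000)
#>   duration cut (90th centile):    20.50 min/hr (n=1000)
#>   nadir cut (10th centile):       80.00% (n=1000)
#>   O2 fraction quartile bounds:    0.125, 0.263, 0.417
```

So in this simulated cohort a patient is "nadir-desaturated" below 80%, and
"long-duration" when spending at least 20.5 min of each monitored hour below
the 97% median cutoff. Fitting the outcome model with change-in-estimate
selection (the exposure terms are never removable):

```r
analysis <- merge(ph$exposures, cohort$patients, by = "patient_id")
m <- change_in_estimate_selection("early_prc", c("nadir_low", "o2_quartile"),
                                  c("copd", "neuro_disease", "smoking"),
                                  analysis)
m
#> <prc_model> early_prc ~ nadir_low + o2_quartile
#>         term   aor ci_low ci_high   wald_p
#>  (Intercept) 0.050  0.027   0.094 2.35e-20
#>    nadir_low 1.919  0.984   3.744 5.59e-02
#>  o2_quartile 1.141  0.914   1.424 2.45e-01
#> c-statistic 0.567 (SE 0.037); Hosmer-Lemeshow p 0.799; omnibus p 0.0693
m$ledger
#>   step          term      wald_p       delta  action
#> 1    1 neuro_disease 0.836110066 0.002921286 dropped
#> 2    2       smoking 0.235222960 0.023323540 dropped
#> 3    3          copd 0.003042776 0.030771884 dropped
```

The estimated adjusted odds ratio for nadir desaturation (1.92) recovers the
generating log-odds of 0.7 (AOR 2.01) within sampling error at n = 1000, and
the ledger shows why each candidate covariate left the model: none of them
shifted the exposure estimate by more than 10% on the log scale. The whole
flow (simulate → metrics → thresholds → univariate → fit → match → report)
is available as `run_pipeline(pipeline_config(...))`, with a thin CLI at
`inst/cli/pacudesat.R`.

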