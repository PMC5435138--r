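Package: pacudesat
Title: Phenotyping Post-Anesthesia Care Unit Desaturation and Early
    Respiratory Complications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving population-centile desaturation phenotypes
    from per-minute post-anesthesia care unit (PACU) pulse-oximetry streams
    and relating them to early postoperative respiratory complications and
    resource utilization. Implements the four stream-level desaturation
    measures (median of sliding-window medians, minutes below a saturation
    level per hour, nadir saturation, and duration of supplemental oxygen
    therapy), population threshold derivation, Table-1 style univariate
    statistics with Woolf confidence intervals, change-in-estimate covariate
    selection for logistic regression with a full diagnostics battery
    (c-statistic, Hosmer-Lemeshow, variance inflation, condition indices),
    interaction and stratified models, and 1:1 greedy propensity-score
    matching without replacement with balance verification. A synthetic
    cohort generator with a nurse oxygen-response mechanism provides ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car
Config/testthat/edition: 3
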