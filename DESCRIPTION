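Package: bptriage
Title: Triage Zones and Cascade Strategies for Hypertension Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a three-zone triage framework for diagnosing
    hypertension from office and home blood pressure, with daytime
    ambulatory blood pressure as the reference standard. Office and home
    readings are aggregated under standardized clinical protocols,
    ROC-based lower (95% sensitivity) and upper (95% specificity)
    cut-offs define a normotension / intermediate / hypertension zone
    partition, and three cascade strategies (OBP-ABP, OBP-HBP-ABP,
    HBP-ABP) escalate intermediate-zone subjects to confirmatory
    measurement. Includes exact binomial (Clopper-Pearson) confidence
    intervals for the diagnostic metric panel, count-table evaluation of
    published phenotype-by-zone distributions, and a calibrated synthetic
    cohort generator with correlated office, home, and ambulatory
    pressures for end-to-end testing.
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
    withr
Config/testthat/edition: 3
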