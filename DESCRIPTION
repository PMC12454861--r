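Package: ThreshLink
Title: Subgroup-Specific Threshold Optimization for Diagnostic AI Scores
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Links achievable sensitivity of a diagnostic AI system,
    estimated by multi-reader ROC analysis on a pathology-enriched
    validation cohort, to the alert rates the same system would produce
    in clinical routine subgroups, and selects subgroup-specific
    operating thresholds by a slope criterion: sensitize until one more
    percentage point of sensitivity costs more than one percentage point
    of alert rate. Includes pooling of 5-point Likert reader ratings into
    nested binary reference standards, per-reader ROC curves with Youden
    cutpoints, empirical and closed-form sensitivity-to-alert-rate
    linkage curves, diagnostic 2x2 metrics with Wald confidence
    intervals, reconstruction of contingency tables from published
    summary statistics, and a seeded synthetic-cohort generator with
    analytic oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, StatisticalMethod, Software
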