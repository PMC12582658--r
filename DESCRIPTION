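Package: ttemulate
Title: Target Trial Emulation with Registry Data and Inverse Probability Weighting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to emulate a pragmatic target trial of starting versus not
    starting a drug class after an index hospitalization, using linked
    registry-style tables (admissions, dispensations, diagnoses, deaths,
    outcome events). Covers cohort construction with ordered eligibility
    screening and an exclusion flowchart, dispensation-based adherence
    episodes with a grace period, per-protocol censoring, discrete-time
    pooled logistic hazard models with restricted cubic spline time,
    unstabilized inverse probability of treatment and censoring weights,
    per-arm cumulative incidence with risk differences and ratios,
    nonparametric bootstrap confidence intervals, and standardized mean
    difference balance diagnostics. Includes a synthetic registry generator
    with a fully known data-generating process and Monte Carlo oracles for
    counterfactual risks, so every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    arrow
Config/testthat/edition: 3
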