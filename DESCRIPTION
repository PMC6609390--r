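Package: coagverify
Title: Rule-Based Autoverification Engine for Coagulation Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A configurable autoverification rules engine for routine
    coagulation panels (PT, APTT, TT, FBG, with optional INR). Implements
    the staged decision process used by clinical laboratory information
    systems: quality-control gating with Westgard multirules, instrument
    error-flag screening, critical-value detection, limited-range checks
    with patient-context customization (anticoagulant therapy, thrombolysis,
    late pregnancy), delta-check rescue against patient history, and
    whole-sample logical (clot-pattern) rules. Also provides the supporting
    machinery a laboratory needs to build and validate such a system:
    percentile-based derivation of autoverification limits from historical
    archives, confusion-matrix validation metrics (sensitivity, specificity,
    passing rates with confidence intervals), turnaround-time comparison via
    the Mann-Whitney U test, and a seeded synthetic-data generator producing
    fully labelled panels, histories, QC series and turnaround records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
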