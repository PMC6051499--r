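Package: centiloidr
Title: Centiloid Calibration and Positivity Thresholds for Amyloid PET
Version: 0.1.0
Authors@R: person("centiloidr", "developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for standardizing amyloid PET quantification on the
    Centiloid scale. Implements quantification primitives (windowed SUVr,
    Logan reference-tissue graphical analysis, geometric-transfer-matrix
    style partial-volume correction, mean cortical indices), level-2
    Centiloid calibration with fit diagnostics, three amyloid-positivity
    threshold estimators (empirical conversion, young-control specificity
    percentile, and a reliable-worsening rule based on LOESS-smoothed
    annualized rates with bootstrap bands), cross-sectional and
    longitudinal cohort statistics including intra-individual variability,
    effect size and hypothetical-trial sample size, and synthetic cohort
    generators so every stage is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
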