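Package: whiskerbias
Title: Value-Modulated Somatosensory Processing in Go/No-Go Whisker Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for single-unit electrophysiology recorded while
    mice perform Go/No-Go (discrimination) or Go/Go (detection) whisker tasks.
    Provides touch-aligned spike binning and z-scoring, a time-resolved
    neurometric d-prime ("stimulus bias") statistic, responsive /
    preference / facilitated-vs-suppressed unit classification, cross-correlogram
    lag analysis of facilitation versus suppression, behavioral-context
    (Miss/Away) modulation with feature-occupancy-matched resampling controls,
    baseline-rate-to-reaction-time correlation, whisker kinematics (angle,
    Menger curvature, ROI-based touch detection), and a synthetic-session
    generator with ground-truth records for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
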