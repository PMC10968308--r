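Package: ecgsqi
Title: Real-Time Signal-Quality Classification for Wearable Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Template-referenced, threshold-based quality classification of
    single-lead ECG recordings from wearable monitors. The classifier screens
    consecutive 2 s windows against a per-recording reference template
    (maximum, minimum and standard deviation of the first stable 10 s period)
    using three rejection rules - near-saturation peak-to-peak range, a
    low-amplitude floor relative to the template range, and excess standard
    deviation - then aggregates window verdicts into 10 s acceptable or
    unacceptable sample labels by prevalence. Includes a streaming classifier
    equivalent to the batch path, a seeded synthetic ECG and artifact
    generator (baseline wander, electrode-loss saturation, muscle noise,
    flatline, 50 Hz powerline interference) with ground-truth labels, and
    diagnostic-test evaluation (sensitivity, specificity, predictive values,
    likelihood ratios, efficiency, Wald confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
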