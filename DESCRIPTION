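Package: edastress
Title: Electrodermal Activity Stress Analysis from Wearable GSR Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for galvanic skin response (GSR / electrodermal
    activity) recordings from low-cost ADC-based sensors. Converts raw ADC
    counts to skin conductance in microSiemens through the sensor's
    voltage-divider equivalent circuit, extracts the phasic component by
    local-baseline subtraction, detects and characterizes skin conductance
    responses (onset, peak amplitude, rise time, half-recovery time), applies
    a rule-based stressed / not-stressed / invalid categorization with cohort
    summaries, and provides a k-means pseudo-labeling plus SVM/NuSVM
    classification layer with cross-validated grid search. A synthetic-cohort
    simulator with ground-truth event labels makes every stage testable
    without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
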