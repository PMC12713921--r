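Package: sleepval
Title: Validation of Wearable Sleep Staging Against Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating epoch-by-epoch and night-level agreement
    between a wearable sleep-staging device and reference polysomnography.
    Implements hypnogram containers and stage-scheme collapsing, overnight
    sleep-measure derivation (total sleep time, wake after sleep onset,
    sleep efficiency, sleep onset latency, number of awakenings, stage
    durations), discrimination and agreement statistics (sensitivity,
    specificity, predictive values, pooled and average-method Cohen's
    kappa, linearly weighted kappa) with participant-level cluster
    bootstrap confidence intervals, and Bland-Altman analysis with
    proportional-bias and heteroscedasticity-aware limits of agreement.
    A Markov-chain paired-hypnogram simulator with known ground truth
    supports end-to-end testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
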