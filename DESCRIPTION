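Package: oculoemg
Title: Dual-Modality Electrooculogram and Surface EMG Interface Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and offline analysis of a dual-modality assistive
    human-computer interface driven by electrooculogram (EOG) eye-movement
    signals and facial surface electromyogram (sEMG) bursts recorded from a
    shared cross-channel electrode montage. Provides a seeded six-channel
    signal generator (DC and AC EOG pairs plus two sEMG channels), Butterworth
    filtering and rectified moving-average activity detection, per-user
    threshold calibration, a four-step DC/AC saccade state machine with
    baseline-drift renewal, an integrated five-class recognizer with
    involuntary-blink rejection, trial evaluation with summary statistics,
    and division-selection / auto-scan speller simulations for throughput
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
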