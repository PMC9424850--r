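Package: tapfatigue
Title: Shoulder-Muscle Fatigue, Movement Stability and End-Point Accuracy
    for Repetitive Tapping Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement and analysis chain for quantifying how worktable
    height and elapsed time affect shoulder-muscle fatigue, movement
    stability and end-point accuracy during a repetitive four-target
    tapping task. Provides surface-EMG conditioning (zero-phase Butterworth
    band-pass, windowed RMS as percent of maximum voluntary contraction,
    median-frequency fatigue tracking), an agonist/antagonist cocontraction
    index, cycle segmentation and time normalisation of body-worn
    accelerometry, kinematic variability, local dynamic stability via
    principal-component state-space reconstruction and Rosenstein-style
    largest-Lyapunov-exponent estimation at four horizons, end-point
    accuracy and precision scoring, and the bin/period repeated-measures
    statistics that tie the indices together. A synthetic session generator
    plants known fatigue rates, variability, divergence exponents and tap
    dispersion so that every stage of the pipeline is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    pracma,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
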