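Package: pacband
Title: Phase-Amplitude-Coupling-Driven Adaptive Band Filters for ECoG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Adaptive selection of task-relevant high-gamma sub-bands in
    electrocorticography (ECoG) recordings, driven by event-related
    phase-amplitude coupling (ERPAC). Low-frequency rhythms (delta, theta,
    alpha, beta) are used to locate narrow high-gamma carriers whose
    amplitude they modulate; the selected sub-bands form a per-rhythm
    filter bank whose mixed outputs feed a compact split-branch
    convolutional decoder (PACNet). Includes zero-phase Butterworth
    filtering and Hilbert analytic-signal extraction, the circular-linear
    ERPAC statistic, Savitzky-Golay peak picking and band selection, a
    synthetic generator of phase-amplitude-coupled trials, EDF/epoching
    utilities, and a stratified repeated k-fold evaluation harness with
    paired one-sided testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
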