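Package: betarec
Title: Beta-Band LFP Dynamics and rTMS Recognition-Memory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-arm study of low-beta oscillations and
    recognition memory. The electrophysiology arm simulates labelled local
    field potential (LFP) trial epochs, computes baseline-RMS-normalised
    Morlet time-frequency power, tests pre- versus post-sample power changes
    with a median-difference max/min-statistic permutation procedure that
    controls family-wise error, and estimates per-frequency post-peak power
    gradients compared across hit and miss trials. The behavioural arm
    generates block/session designs with beta-frequency and constrained
    random repetitive transcranial magnetic stimulation (rTMS) pulse
    schedules, simulates confidence-rated old/new responses from a
    dual-process signal-detection (DPSD) generative model, builds cumulative
    confidence receiver operating characteristics (ROCs), fits the DPSD model
    by least squares to extract recollection and familiarity indices, and
    derives within-block and between-block stimulation-effect measures.
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
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
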