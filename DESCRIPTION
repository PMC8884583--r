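Package: ictrack
Title: Channel-Wise Seizure Detection, Tracking and Onset-Zone Lateralization from Scalp EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and tracks epileptic seizure activity in multichannel scalp
    EEG using a channel-wise deep network: a shared 1D convolutional encoder
    applied to one-second windows of each electrode, a shared bidirectional
    LSTM tracker across windows, and a softmax classifier producing per-channel
    seizure probabilities.  Channel probabilities are aggregated by max-pooling
    into a recording-level detection trace, and onset-weighted aggregation
    yields a per-electrode seizure-onset-zone map with hemisphere (left/right)
    and head-region (anterior/posterior) scores.  Includes EDF input/output,
    the standard clinical preprocessing chain (bandpass, artifact clamping,
    z-normalization, windowing), training with leave-one-patient-out
    cross-validation, false-alarm-budget threshold calibration, event-based
    scoring (false positives per hour, sensitivity, detection latency), and a
    seedable synthetic ictal EEG generator for end-to-end testing without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
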