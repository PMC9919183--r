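Package: mfbeat
Title: Matched-Filter Convolutional Networks for Inter-Patient ECG Beat
    Classification
Version: 0.1.0
Authors@R:
    person("mfbeat", "maintainers", email = "mfbeat@example.org",
           role = c("aut", "cre"))
Description: Tools for heartbeat-level arrhythmia classification on
    single-lead ECG with an inter-patient train/test division. Implements
    matched-filter template extraction from class-averaged beats, a tiny
    one-layer 1-D convolutional correlator network with global max
    sampling fused with causal dynamically normalized RR-interval
    features, class-imbalance-weighted training, per-class and macro
    evaluation, and additive-noise robustness sweeps. Includes a seeded
    synthetic ECG generator, a reader for WFDB-style annotated records,
    and a plain-text fixture dialect so the full pipeline is testable
    without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
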