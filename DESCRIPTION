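Package: msretest
Title: Microstate Test-Retest Reliability for Evaluating EEG-fMRI Noise Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for attenuating residual ballistocardiogram (BCG) artifacts
    in EEG recorded during simultaneous fMRI, and for evaluating noise
    reduction through the test-retest reliability of EEG microstate metrics.
    Implements joint decorrelation (generalized eigendecomposition contrasting
    heartbeat-locked and reference covariances) with noise-ratio rescaled
    eigenvalue thresholding, a standard EEG preprocessing chain (Butterworth
    and FIR filters, gradient-artifact average subtraction, carbon-wire-loop
    regression, spectral segment rejection, average reference, bad-channel
    interpolation), microstate analysis (GFP-peak topographies, two-level
    AAHC clustering, template ordering, backfitting with temporal smoothing,
    duration/occurrence/coverage/transition metrics), absolute-agreement
    intraclass correlation with Fisher-z aggregation and permutation testing,
    a threshold-sweep selection workflow, and a ground-truthed synthetic data
    generator for end-to-end validation. Reads and writes BrainVision and
    EDF+ recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
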