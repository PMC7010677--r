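Package: tremornet
Title: Separation of Voluntary Motion and Pathological Hand Tremor with
    Bidirectional Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates the voluntary component of hand motion from
    pathological hand tremor (3-14 Hz) in accelerometer time series.
    Fits a deep bidirectional gated-recurrent-unit (GRU) network with
    fully independent forward (online, one-sample-ahead predictive) and
    backward (offline) paths, trained on pseudo-synthesized action
    tremor with a shifted-target strategy.  Includes a synthetic
    action-tremor generator with subject-wise train/validation/test
    splits, band-limited multiple Fourier linear combiner (BMFLC and
    extended BMFLC) adaptive-filter baselines, and an evaluation suite
    with endpoint errors, sliding-FFT power spectral densities, and
    population-level spectral statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
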