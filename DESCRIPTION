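Package: icpratio
Title: Automated P2/P1 Subpeak Ratio Monitoring from Intracranial Pressure Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a raw 100 Hz intracranial-pressure (ICP) recording into a
    postprocessed series of P2/P1 subpeak amplitude ratios, a bedside indicator
    of cerebral compliance. The pipeline band-pass filters the signal, detects
    heartbeat pulse onsets with a multiscale (modified Scholkmann) trough
    detector, normalizes each beat to a 180-sample template, discards pulses
    without a calculable ratio using a trainable sequence classifier (1-D CNN,
    bidirectional LSTM, or LSTM-FCN), designates the P1 and P2 subpeaks from a
    learned per-sample score density optionally restricted to curvature-derived
    candidates (1-D U-Net or bidirectional LSTM), and smooths the resulting
    ratio stream with an outlier-rejecting sliding window. A synthetic ICP
    record generator with full ground truth supports training and validation
    without patient data. Neural-network training (Adam, binary cross-entropy
    and mean-squared-error objectives) is implemented in the package with
    single-precision compiled kernels for the recurrent layers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
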