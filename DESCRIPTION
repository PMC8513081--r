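Package: mdbci
Title: Multi-Domain Convolutional Networks for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end decoding of motor-imagery EEG with a multi-domain
    convolutional network: trials are re-expressed in three parallel domains
    (raw time series, multiclass common-spatial-pattern projections obtained by
    joint approximate diagonalization, and instantaneous phase from the
    discrete Hilbert transform), classified by three shallow convolutional
    branches fused through a fully connected head, and trained on cropped
    sliding windows. Includes readers for BrainVision, EDF and GDF recordings,
    Butterworth preprocessing, stratified k-fold evaluation with binomial
    chance-level confidence limits, and a synthetic EEG generator emulating
    dry- versus wet-electrode signal-to-noise conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
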