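Package: ecgwave
Title: Single-Lead ECG Denoising, Delineation and T-Wave Alternans Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for single-lead electrocardiogram (ECG)
    analysis. A denoising auto-encoder reconstructs clean 370-sample beats
    from noisy input; a convolutional bidirectional-LSTM delineator labels
    every sample of a beat as P-wave, QRS-complex, T-wave, isoelectric line
    or zero-padding; and a T-wave-alternans (TWA) detector quantifies
    beat-to-beat T-peak alternation from the even/odd T-peak difference
    series using a zero-crossing criterion with a heart-rate gate. Includes
    a labeled synthetic-ECG beat generator with SNR-controlled noise
    injection so the whole pipeline is trainable and testable offline,
    minimal WFDB-compatible record I/O, and per-class evaluation metrics
    (confusion matrix, sensitivity/specificity/precision/F1, ROC and
    precision-recall curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
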