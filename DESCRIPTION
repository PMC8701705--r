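Package: nncondense
Title: Neural Network Condensation for Clinical Time-Series Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building, condensing and evaluating small neural
    networks for in-hospital mortality prediction from irregular ICU event
    streams. Implements a two-layer LSTM baseline, a hidden-kernel LSTM
    (hLSTM) cell that folds two recurrent layers into one, quantile-based
    channel pruning with surgical weight removal and retraining, and
    post-training uniform affine 8-bit quantization. Includes a synthetic
    ICU cohort generator and the standard clinical time-series
    preprocessing pipeline (regular-interval resampling, forward-fill and
    normal-value imputation, observation masks, one-hot encoding and
    z-normalization), so the full condensation workflow is testable
    end-to-end without access-restricted clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
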