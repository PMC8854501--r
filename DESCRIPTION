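Package: tofrcast
Title: Patient-Specific One-Step-Ahead Forecasting of Train-of-Four Ratio Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for real-time, patient-specific forecasting of the
    train-of-four ratio (TOFR) during recovery from nondepolarizing
    neuromuscular block. Provides a synthetic cohort generator with
    demographically modulated sigmoid recovery curves, one-step-ahead
    recurrent sequence models (simple recurrent, gated recurrent unit, and
    long short-term memory cells trained by backpropagation through time),
    transfer learning by patient similarity on age and body-mass index, and
    an evaluation harness covering per-patient prediction, pairwise
    similar-versus-dissimilar donor comparison, and leave-one-out
    cross-validated transfer.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
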