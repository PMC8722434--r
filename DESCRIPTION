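Package: eegfp
Title: Specificity and Permanence of EEG Functional-Connectivity Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state EEG functional-connectivity
    fingerprinting. Simulates longitudinal multi-subject cohorts of 32-channel
    EEG-like recordings with subject-specific directed coupling and
    session-to-session drift; preprocesses them (zero-phase band-pass and notch
    filtering, Hjorth nearest-neighbour surface Laplacian, fixed-length
    segmentation); estimates per-epoch connectivity as pairwise Granger
    causality from bivariate autoregressive fits and as histogram-based mutual
    information; identifies subjects with a one-against-one RBF support-vector
    machine both within sessions (stratified ten-fold cross-validation) and
    across sessions recorded up to six months apart; and localizes the most
    subject-specific connections by scalp region via linear margin-weight
    aggregation or permutation importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
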