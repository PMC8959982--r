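Package: plvnet
Title: Phase-Locking Brain Networks and Multilayer Graph Attributes for
    Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds band-resolved functional brain networks from multichannel
    resting-state EEG using the phase-locking value (PLV) computed from complex
    Morlet wavelet phase, binarizes them by a connection-strength threshold, and
    extracts node-level graph attributes (degree, clustering coefficient, local
    efficiency, connectivity robustness) for single-layer, multilayer, and
    power-spectrum-weighted ("improved") multilayer networks. Welch-Hamming
    spectral band powers and band-power ratios supply the multilayer weights and
    a non-network feature set. Filter-style feature selection and soft-voting
    tree ensembles (random forest plus two gradient-boosted tree models) under
    stratified 10-fold cross-validation classify two subject groups. A seeded
    synthetic EEG cohort generator with controllable band power and pairwise
    phase coupling makes the full pipeline testable without clinical data; EDF
    import/export is included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    randomForest,
    xgboost,
    e1071,
    class,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
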