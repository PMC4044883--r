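Package: mildrem
Title: Pre-miRNA Hairpin Classification via Linear Dimensionality
    Reduction with Explicit Feature Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies pre-microRNA hairpins against pseudo hairpins and
    other non-coding RNAs using two-class Gaussian models, linear
    dimensionality reduction (Fisher, heteroscedastic and Chernoff
    discriminant criteria) and a Gaussian-Bayes decision rule, after
    explicitly mapping features to a higher-dimensional space with a
    degree-2 polynomial expansion or randomized Fourier features that
    approximate a Gaussian RBF kernel.  Includes imbalance-aware
    evaluation (sensitivity, specificity, geometric mean) under
    stratified k-fold cross-validation, beam-style wrapper feature
    selection with result caching, (gamma, nComponents) grid search,
    native computation of sequence-composition features from FASTA, a
    synthetic-data generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
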