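Package: ampbench
Title: Negative-Data Sampling Bias in Antimicrobial Peptide Prediction
    Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the choice of negative (non-AMP) training
    data biases benchmarks of antimicrobial peptide (AMP) predictors.
    Implements eleven published negative-sampling strategies over an
    annotated protein database as one configurable engine, ten classical
    AMP-prediction architectures (amino-acid composition, pseudo-amino-acid
    composition, CTD distribution descriptors, physicochemical panels,
    n-grams with exact permutation-test selection, Lempel-Ziv similarity
    profiles; random forests, support vector machines and fuzzy k-nearest
    neighbours), a full train-on-one/benchmark-on-all AUC grid, and the
    downstream bias diagnostics (diagonal versus off-diagonal AUC, MAD
    ratios, composition- and length-distance correlations, grouped
    nonparametric tests). A seeded synthetic-data module generates
    AMP-like positives and a keyword/localization-annotated background
    database so the whole experiment runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    dplyr,
    e1071,
    ranger,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
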