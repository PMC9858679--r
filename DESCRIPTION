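Package: genochain
Title: Multi-Label Multi-Class Genetic Disorder Prediction with
    Classifier Chains and Stacked Tree-Ensemble Probability Features
Version: 0.1.0
Authors@R:
    person("Genochain", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for predicting a patient's genetic disorder class
    (mitochondrial, multifactorial, single-gene) together with its nine-way
    disorder subclass from clinical-genomic tabular records. Implements a
    schema-driven CSV reader for the 44-column genomes patient table, the
    fixed feature-drop and integer category-encoding pipeline, random
    undersampling for class balance, a from-scratch classifier chain over
    the 12 binarized classes, a hybrid feature constructor that stacks
    extra-trees and random-forest class probabilities (with out-of-fold
    construction to prevent leakage), Jaccard-family multi-label metrics
    (Hamming loss, row-Jaccard accuracy, alpha-evaluation score, per-label
    macro precision/recall/F1), a synthetic patient-table generator with a
    planted disorder-to-subclass hierarchy, and an experiment-grid runner
    with a command-line interface. Tree ensembles (decision tree, random
    forest, extra trees) are provided by a compiled CART implementation in
    the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    FNN,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
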