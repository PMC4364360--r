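Package: rsbpnn
Title: Rough-Set Feature Selection with Backpropagation Neural Network
    Classification for Clinical Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage knowledge-mining workflow for clinical decision
    support. Stage one cleans a categorical information system
    (rejection and class-conditional mode imputation of missing values,
    cut-point discretization) and selects attribute subsets by the rough-set
    indiscernibility relation: exhaustive enumeration of candidate subsets,
    acceptance by equality (or thresholded pairwise similarity) of the
    induced partition with the full-attribute partition on the positive
    region, plus core extraction and subset counting. Stage two trains a
    from-scratch single-hidden-layer backpropagation neural network
    (tangent-sigmoid hidden units, linear output) on the reduct-projected
    features and evaluates it with confusion-matrix metrics, ROC curves and
    AUC under seeded train/test splits and k-fold cross-validation. A
    synthetic-data generator with planted minimal reducts, controlled
    decision inconsistency and injected missingness makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
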