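Package: rpifuse
Title: Multi-Feature Fusion Prediction of lncRNA-Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts lncRNA-protein interactions from four complementary
    information sources: stacked k-mer frequencies of the RNA sequence,
    conjoint-triad group k-mer frequencies of the protein sequence,
    cosine-transform compression of secondary-structure strings,
    reduced physicochemical descriptors, and principal-component
    projections of a protein-protein interaction score matrix.
    Feature blocks are screened by random-forest Gini importance and
    classified with a parallel multi-branch one-dimensional convolutional
    network with concatenate or stacking fusion. Includes a full
    evaluation suite (accuracy, sensitivity, specificity, precision,
    F1, MCC, rank-based AUC, ROC/PR curves, stratified five-fold
    cross-validation) and a synthetic-data generator with a planted,
    recoverable interaction signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
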