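Package: ppiMerge
Title: Stacked Merging of Protein-Protein Interaction Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stacking pipeline for protein-protein interaction (PPI)
    prediction. Scores candidate protein pairs with a grid of base
    classifiers -- phylogenetic-profile co-occurrence, mutual-information and
    hypergeometric scorers under several reference-taxa selection strategies,
    and Gene Ontology pair-feature learners (naive Bayes, random forests)
    over several GO aspect combinations and training networks -- then merges
    the per-pair classification scores with a random-forests meta-learner.
    Includes gold-standard construction with random-pairing negative
    sampling, trapezoidal ROC/AUC evaluation over repeated stratified
    splits, and a fully synthetic multi-species data generator with planted
    co-evolution and GO term-sharing signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ranger,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
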