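Package: pssmclass
Title: Protein Structural Class Prediction from PSSM Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the structural class of a protein (all-alpha, all-beta,
    alpha/beta, alpha+beta) from its PSI-BLAST position-specific scoring
    matrix (PSSM). Profiles are sigmoid-scaled and summarised as gapped
    dipeptide compositions (GapDPC), features are ranked by linear SVM
    recursive feature elimination (SVM-RFE), and an RBF-kernel support
    vector machine with grid-searched hyperparameters performs the
    classification. Includes jackknife (leave-one-out) and stratified
    k-fold evaluation with per-class accuracy and Matthews correlation,
    a parser and writer for PSI-BLAST ASCII PSSM files, seeded synthetic
    profile and feature-table generators for testing, and a command-line
    interface chaining the stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
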