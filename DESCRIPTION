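Package: nephroquiz
Title: Decision-Tree Case Quizzes for Categorical Diagnosis Training
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Induces C4.5-style decision trees (entropy, gain ratio,
    multiway nominal splits, pessimistic-error pruning) over categorical
    case tables such as renal-biopsy report spreadsheets, validates them
    by stratified k-fold cross-validation (accuracy, Cohen's kappa), and
    turns each root-to-leaf path into an ordered diagnostic quiz for
    e-learning: sessions are graded against the tree, learners advance
    levels under a 70% rule, and cohorts are ranked. Includes a
    ground-truth-tree synthetic case generator for recovery experiments,
    plus CSV/ARFF input and JSON model persistence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
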