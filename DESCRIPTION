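Package: multipep
Title: Multi-Label Therapeutic Peptide Function Prediction with Label-Embedding Transformers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the functional repertoire of therapeutic peptides as a
    multi-label classification problem. Peptide sequences are embedded by a
    Transformer encoder over residues while each candidate function is carried
    as a learnable label token through a Transformer decoder, so that functions
    exchange correlation information via attention before per-function linear
    classifiers make the calls. Includes the two-phase training procedure
    (shared single classifier, then frozen label embeddings with
    function-specific classifiers), a multi-label classifier-retraining
    strategy based on square-root bootstrap rebalancing for incompletely
    annotated (weak-label) data, a full multi-label evaluation suite
    (example-based accuracy, macro-F1, AUC, MCC, RkCC, shot-group reports,
    correlation and attention summaries), sequence encoders for one-hot and
    PSI-BLAST PSSM features, and a synthetic motif-based benchmark generator
    so every component is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
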