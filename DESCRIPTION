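Package: pairppi
Title: Pair-Input Protein-Protein Interaction Prediction with Stringent
    Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable framework for sequence-based protein-protein
    interaction (PPI) prediction treated as a pair-input learning problem.
    Builds stringent benchmark datasets from curated interaction evidence
    (confidence and interaction-type filtering, identity-filtered negative
    sampling at a configurable class ratio), partitions labeled pairs into
    C1/C2/C3 strata by held-out-protein membership so that generalization
    to unseen proteins can be measured honestly, encodes protein pairs
    symmetrically via the Hadamard product over pluggable per-protein
    feature sources (amino-acid composition, dipeptide composition, or
    pre-computed language-model embedding tables), trains multilayer
    perceptron, random forest, or support vector machine classifier heads,
    and evaluates them with an imbalance-aware metric suite
    (precision-recall and ROC curves, AUPR/AUROC, Matthews correlation).
    Includes a seeded synthetic latent-factor interaction world for
    end-to-end testing without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
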