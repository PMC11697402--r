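Package: netbench
Title: Benchmarking and Consensus Construction for Molecular Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to standardize, characterize, and benchmark collections of
    gene and protein interaction networks. Implements edge-list
    standardization and top-score filtering; representation-bias statistics
    (annotation-skew permutation tests, interaction-density matrices,
    tissue-specificity classification, term-enrichment utilities); gene-set
    recovery benchmarking by random-walk-with-restart propagation with
    subsampled AUPRC, degree-matched shuffled null models, robust Z scores,
    size adjustment, and centralized ranks; global and ranked consensus
    (composite) network construction with per-edge support annotation; L3 and
    MPS topological interaction prediction evaluated by cross-validated and
    external-set precision-at-k; scoring of externally detected communities
    against reference complexes; aggregation of structure-model confidence
    scores; and synthetic-data generators so the full pipeline runs without
    any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
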