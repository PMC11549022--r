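Package: painrank
Title: Pain Gene Prioritization from Multi-Omics and Interaction Network Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-centred prioritization of candidate pain genes. Engineers a
    gene-by-feature matrix from genomic annotations, Gene Ontology terms
    (TF-IDF and principal components), composite log-fold-change summaries of
    multi-omics experiments, and eleven protein-protein interaction network
    centrality features (including stress, radiality, and the topological
    coefficient). Trains an imbalance-aware weighted soft-voting ensemble of
    tree learners, aggregates SHAP attributions across members, emits a
    per-gene pain score, and validates the ranking with leakage-removed
    running-sum enrichment statistics and decile over-representation tests.
    Ships a synthetic-cohort generator with planted network hubs, enriched
    ontology terms, and concentrated expression effects so that every stage of
    the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
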