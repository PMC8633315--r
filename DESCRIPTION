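Package: phenospace
Title: Encoding, Embedding and Neighbor-Based Evaluation of Ontology
    Phenotype Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing cohorts of ontology-annotated phenotype
    profiles such as mouse models and human diseases. Parses OBO
    ontologies and exposes the is-a DAG; encodes profiles as
    ancestor-closed binary vectors, Bayesian real-valued vectors, or
    information-content-weighted k-mer text bags; computes exact nearest
    neighbors and low-dimensional embeddings (neighbor-graph manifold
    layout and PCA); projects term sets and diseases into embeddings; and
    evaluates embeddings with neighbor-based phenotype prediction,
    Fisher-test region enrichment, same-gene neighbor statistics with an
    analytic null, disease causal-gene recovery, center-bias diagnostics
    and cross-embedding neighbor Jaccard consistency. Includes a seeded
    synthetic-data generator (ontologies, model cohorts, diseases) so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
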