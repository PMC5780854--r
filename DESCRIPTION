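Package: infacront
Title: Cross-Ontology Term Similarity via Information Flow on Term-Gene-Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes similarities between terms drawn from two different
    biomedical ontologies (for example Gene Ontology sub-ontologies, the
    Disease Ontology or the Human Phenotype Ontology). Ontology annotations
    and a gene functional-interaction network are combined into a weighted
    term-gene-gene network; information flow through the network is modeled
    by a damped random walk (emitting, absorbing and channel models), each
    term is represented as a vector of expected gene visits, and term pairs
    are scored with a weight-adjusted cosine. Also provides a vector-space
    model baseline, TF-IDF scoring of co-occurrence count matrices, a
    ROC/AUC benchmark harness with repeated negative sampling, and a seeded
    synthetic-data generator that writes OBO, GAF and edge-list fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
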