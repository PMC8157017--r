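Package: linkscore
Title: Link Prediction in Undirected Complex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting missing links in undirected networks.
    Provides an assembled-network store with lazy non-edge enumeration,
    graph traversal and Dijkstra shortest paths with landmark-based
    approximate distances, topological-similarity link predictors
    (common neighbours, Adamic-Adar, resource allocation and variants),
    graph-embedding encoders (Laplacian eigenmaps, edge-wise matrix
    factorization, node2vec random-walk skip-gram) composed with a
    logistic classifier or vector-similarity measures, and a performance
    evaluation suite with streaming ROC, precision-recall areas under
    trapezoidal and Davis-Goadrich interpolation, top-precision, and a
    seeded multi-run experiment harness. Includes seeded random-graph
    generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    Rcpp,
    rlang,
    tibble,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
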