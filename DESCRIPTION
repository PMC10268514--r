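Package: gsomata
Title: Topological Clustering of Expression Profiles by Graph-Based Stochastic Self-Organizing Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clusters cells (or tissue sections) from their transcriptome
    profiles onto a user-supplied cell-domain topology graph using a
    batch-learning stochastic self-organizing map whose mapping layer is the
    graph itself. A replica-exchange Markov chain Monte Carlo search finds the
    gene subset that maximizes a combined score of pairwise adjacency accuracy
    and adjusted Rand index, with simulated-annealing optimization of the
    cluster-to-vertex allocation. Includes multi-run consensus calling of
    topology-discriminating genes, virtual gene knockout ranking,
    hypergeometric enrichment, and a seeded synthetic single-cell benchmark
    generator with linear, cycle, bifurcating, branching and disconnected
    backbones.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    ranger,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
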