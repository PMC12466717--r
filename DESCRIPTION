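Package: treessm
Title: Tree State Space Models for Animal Behavior Recognition from Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hierarchical vision backbone for classifying animal behavior
    from short video clips, built around a tree-structured state space layer
    (TreeSSM). Each frame's feature grid is turned into a 4-connected pixel
    graph weighted by cosine feature similarity, reduced to a minimum
    spanning tree with Boruvka's algorithm, and aggregated by a linear-time
    two-pass scan whose per-pair coefficients are products of edge weights
    along tree paths. The package includes zero-order-hold discretization of
    the state space parameters, a full training loop (Adam, step learning
    rate decay, stochastic depth) with reverse-mode gradients implemented
    natively, frame sampling strategies (uniform and random), a synthetic
    five-class behavior video generator in which some classes differ only in
    their temporal dynamics, and evaluation via confusion matrices and macro
    precision/recall/F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    yaml
Config/testthat/edition: 3
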