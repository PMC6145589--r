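Package: planarnet
Title: Comparative Network Analysis of Planar Biological Distribution Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative structural analysis of planar,
    spatially embedded biological transport networks such as mycelial
    fungi and pial (brain-surface) vasculature. Provides a light-weight
    spatial network container with CSV and GraphML input/output,
    topological metrics (mean degree, clustering, alpha index,
    topological efficiency, edge betweenness), spatially embedded metrics
    (wiring length, global physical efficiency, physical edge
    betweenness), spatial null models (Euclidean minimum spanning tree,
    greedy triangulation, connected degree-preserving rewiring),
    topological and physical Rentian scaling estimation, percolation
    robustness under random edge removal, relative cost/efficiency/
    robustness measures, two-group statistical comparison, and synthetic
    generators that emulate the loopy mycelium-like and sparse
    vasculature-like regimes of such systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
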