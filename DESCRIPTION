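Package: ddjkm
Title: Community Detection by Density-Degree Seeded k-Means on Jaccard Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community detection for undirected networks with a known number of
    communities K. Nodes are ranked by the product of local BFS-ball density and
    degree centrality; K initial cluster centers are chosen by descending that
    score while spreading seeds apart through a density-weighted Jaccard
    correlation matrix, and communities are obtained by k-means over the rows of
    the node Jaccard similarity matrix. Includes partition-agreement metrics
    (normalized mutual information and bidirectional best-match F1), an
    LFR-style benchmark generator with power-law degree and community-size
    distributions and a tunable mixing parameter, planted-partition and
    ring-of-cliques fixtures, and a benchmark sweep driver.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    withr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
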