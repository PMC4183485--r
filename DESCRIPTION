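Package: modcarto
Title: Modular Network Clustering and Node Role Cartography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Partition undirected networks into modules with spectral,
    k-means or Markov (MCL) clustering and characterise every node by its
    within-module degree z-score and participation coefficient, assigning
    one of seven topological roles (R1-R7) in a modified Guimera-Amaral
    cartography whose participation coefficient can reach 1 regardless of
    the number of modules. Includes builders for protein contact networks
    from alpha-carbon coordinates, gene co-expression networks from
    expression matrices, and Erdos-Renyi, Barabasi-Albert and
    planted-partition reference graphs, plus readers and writers for
    whitespace edge-list (.abc) and cluster-index (.idx) files and a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    grDevices,
    graphics,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
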