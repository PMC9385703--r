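Package: foodweblump
Title: Taxonomic Simplification and Topological Comparison of Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for taxonomy-based simplification of directed food webs
    (prey-to-predator graphs): node lumping across ordered resolution levels
    with edge-weight merging, node-level topological indices (degree,
    betweenness, closeness, trophic level, Katz centrality) with min-max
    normalization, global clustering and flow-hierarchy measures, value-based
    and divisive (Girvan-Newman) community detection, partition-agreement
    scores (Rand, homogeneity, completeness, V-measure, Fowlkes-Mallows),
    and Sankey-style flow tables comparing original versus simplified
    networks. Includes a seeded generator of taxonomically annotated
    synthetic webs and a command-line entry point.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
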