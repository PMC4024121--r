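Package: tspclust
Title: Somatic Mutation Clustering on Protein Structures via
    Traveling-Salesman Linearization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies non-random clusters of somatic missense mutations in
    proteins while accounting for tertiary structure.  The C-alpha backbone is
    realized as a complete Euclidean graph and linearized with traveling-salesman
    insertion heuristics (cheapest, nearest, farthest insertion); mutation
    positions along the resulting Hamiltonian path are tested for clustering
    with an order-statistic test whose null p-values have a closed Beta form,
    followed by an intra-structure Bonferroni adjustment and an across-structure
    rFDR threshold.  Includes PDB C-alpha parsing, structure/sequence numbering
    reconciliation, COSMIC-style mutation table filtering, synthetic fixture
    generators, and path-rearrangement diagnostics.
License: GPL-2
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
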