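Package: netmug
Title: Network-Guided Multi-View Clustering with Individual-Specific Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the netMUG workflow for subtyping individuals from two
    aligned data views and an extraneous phenotype. Features are selected by
    phenotype-supervised sparse multiple canonical correlation analysis
    (SmCCA) with feature subsampling and module detection; individual-specific
    networks (ISNs) are built from leave-one-out perturbations of a
    correlation-plus-phenotype edge score; individuals are clustered by Ward's
    hierarchical clustering with the cluster count detected automatically by a
    dynamic (adaptive) tree cut. Also ships the matching synthetic two-view
    data generator, cluster-level network summaries (mean ISNs, top-edge
    binarization, largest connected component, graph filtration curves) and
    evaluation utilities (adjusted Rand index, Kruskal-Wallis association).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
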