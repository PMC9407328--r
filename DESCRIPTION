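Package: coexhub
Title: Weighted Gene Coexpression Networks and Hub-Gene Screening for
    Quantitative Traits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale reimplementation of the weighted gene coexpression
    network analysis (WGCNA) workflow used to screen trait-associated hub
    genes from bulk RNA-seq FPKM tables: median-absolute-deviation expression
    filtering, Euclidean/UPGMA sample outlier removal, soft-threshold
    selection by scale-free topology fit, topological overlap matrix (TOM)
    construction, dynamic tree-cut module detection with eigengene merging,
    module eigengene to trait correlation with Student asymptotic p-values,
    Cytoscape network export, and a two-stage degree/eigenvector centrality
    hub screen. Includes a latent-factor synthetic transcriptome generator
    with planted modules, hubs, and an outlier sample so every stage is
    verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
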