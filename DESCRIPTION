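Package: micronet
Title: Weighted Co-Occurrence Network Analysis of Paired Microbiome Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Signed weighted co-occurrence network analysis for paired
    (crossover-design) microbiome count tables: OTU filtering and
    normalisation, alpha/beta diversity with NMDS and PERMANOVA, paired
    differential abundance with Benjamini-Hochberg correction,
    soft-thresholded signed adjacency and topological overlap matrices,
    consensus networks across dietary conditions, hierarchical module
    detection with module eigengenes, eigengene-trait consensus
    correlation screening, and LDA-effect-size module-driver
    identification. Includes a Dirichlet-multinomial generator of paired
    synthetic datasets with planted modules, condition effects and trait
    couplings, exporting ground truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    permute,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    mclust,
    optparse
Config/testthat/edition: 3
biocViews: Microbiome, Network, GraphAndNetwork, Clustering, Metagenomics
RoxygenNote: 7.3.3
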