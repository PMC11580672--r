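Package: gliamorph
Title: Microglia Morphometric Phenotyping from Tree Reconstructions and
    Marker Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for unsupervised phenotyping of
    microglia morphology. Reads and validates single-cell tree
    reconstructions in SWC format, extracts a fixed 14-feature
    morphometric panel (skeleton, surface/volume, and graph-centrality
    features), computes topological morphology descriptor (TMD)
    persistence barcodes and persistence images under a radial-distance
    filtration, aggregates cells into bootstrap pseudo-samples, embeds
    them with PCA and UMAP, clusters with Leiden community detection, and
    orders pseudo-samples in pseudotime along a principal graph rooted at
    a control condition. A seeded synthetic-data module generates cohorts
    of 3D microglia morphologies along a homeostatic-to-amoeboid
    reactivity continuum and two-channel marker images with controllable
    inter-channel correlation, so the whole analysis runs without
    external microscopy data. Includes particle counting by
    auto-threshold and watershed, two-channel Pearson colocalization with
    Fisher z intervals, and group comparison by Welch t-test or one-way
    ANOVA with Tukey HSD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    igraph,
    uwot,
    cluster,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
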