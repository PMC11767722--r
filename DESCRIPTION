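Package: vesselflow
Title: Flow-Weighted Network Analysis of In Vitro Vascular Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies remodeling of in vitro microvascular (lumen) networks
    from time series of binary lumen masks. Computes a 2D creeping-flow
    (Stokes) velocity field and wall shear stress directly on the pixel
    lattice, extracts a node-edge vessel graph by homotopic skeletonization,
    weights each edge with a dimensionless wall-shear-stress ratio and
    flow-rate ratio, and summarises network optimization through
    shear-weighted betweenness and flow-weighted strength centralities.
    Includes a synthetic time-lapse generator that emulates the five
    morphological stages of long-term perfusion culture (meshwork, sprouting,
    remodeling, stable, erosion), with flow-dependent pruning of low-flow
    bridging segments, so the whole pipeline is testable without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    EBImage,
    jsonlite,
    tiff,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
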