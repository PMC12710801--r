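Package: morphoflow
Title: Quantitative Live-Imaging Analysis of Branching Epithelial Morphogenesis
Version: 0.1.0
Authors@R: person("Morphoflow", "Developers", role = c("aut", "cre"),
    email = "morphoflow@example.org")
Description: Tools to quantify tissue fluidity and branching morphogenesis from
    3D time-lapse microscopy of epithelial tubules: coarse-grained 3D particle
    image velocimetry with motion-similarity coherence profiles, cell-cluster
    dispersal statistics (standard distance) with trend-comparison inference
    (slope-homogeneity ANCOVA, Hotelling's T-squared with FDR adjustment),
    tubule morphometry (cross-sectional area, division angles, diameter
    distributions), and skeleton-based counting of branching tips. A synthetic
    data module generates advected particle movies, clustered trajectories with
    prescribed dispersal dynamics, and branching-tree images with known ground
    truth so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
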