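Package: cubecyte
Title: Cube-Based Spatial Image Cytometry for 3D Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative image cytometry for 3D (and 2D) fluorescence
    image stacks of biofilms and other spatially structured microbial
    communities.  The segmented biovolume is dissected into a cubical
    grid of user-defined edge length; each occupied cube becomes a
    pseudocell object carrying structural, textural, fluorescence and
    correlation parameters, which can be gated, combined into custom
    parameters, tracked over time and aggregated into spatiotemporal
    kymographs.  Whole-biofilm outputs include COMSTAT-compatible
    structure metrics (biovolume, mean thickness, roughness coefficient,
    surface area), voxel-level colocalization measures and 3D spatial
    correlation functions with cluster-size and separation summaries.
    Results export to CSV and legacy VTK files for rendering in ParaView.
    A seeded synthetic-image generator produces colony-shaped ground
    truth volumes for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
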