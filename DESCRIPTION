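Package: nichemetrics
Title: Quantitative Analysis of Engineered Bone-Marrow Niches
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative characterization of ex vivo bone-marrow
    niche models built on porous protein scaffolds. Provides 3D megakaryocyte
    morphometry on labeled voxel volumes (volume, isosurface area, Wadell
    sphericity, projected area), porosity and local-thickness analysis of
    binary volumes, a Divergence Index over shared-bin cell-size frequency
    distributions with threshold classification, bootstrap uncertainty and
    treatment-response reduction metrics, and the scaffold physical
    characterization computations: swelling, Darcy permeability, amide-II
    band deconvolution with crystallinity index, Thioflavin-T relative
    beta-sheet content, Lorentzian modulus-distribution fitting, strain-sweep
    ultimate strain and tan(delta), and the Rg/Rh shape factor. A seeded
    synthetic-data module generates niche volumes and instrument-like signals
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Software
RoxygenNote: 7.3.3
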