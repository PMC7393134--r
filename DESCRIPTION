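Package: epivertex
Title: Active 3D Vertex Model of Epithelial Shells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of closed single-cell-thick epithelial
    shells with a surface-tension-based three-dimensional vertex model. Cells
    are incompressible prism-like polyhedra with polygonal apical and basal
    sides; the shell encloses an incompressible lumen. The model combines
    overdamped gradient-descent relaxation with active T1 cell rearrangements
    (a threshold-rate scheme and an Ornstein-Uhlenbeck fluctuating
    line-tension scheme) and stochastic cell growth and division, producing
    spherical, stomatocyte, budded, and branched morphologies. Includes shell
    morphometrics (reduced volume, cell height and curvature,
    thickness-modulation index, topological pair correlations, gyration-tensor
    anisometry, morphology classification) and the matching continuum
    elasticity theory for flat-epithelium equilibria and the reduced-volume
    prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
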