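Package: eggshellEBSD
Title: Eggshell Microstructure and Crystallography from EBSD Maps with
    Phylogenetic Comparative Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of avian eggshell calcite microstructure from
    electron backscatter diffraction (EBSD) orientation maps: trigonal
    calcite misorientation algebra, grain segmentation, grain-boundary
    angle classing, ellipse-based aspect-ratio mapping with a median-area
    filter, and neighbour-pair versus random-pair misorientation
    distributions with Type 1 / Type 2 classification. Downstream
    phylogenetic comparative tools estimate Pagel's lambda, fit six
    trait-evolution models with AICc selection, and reconstruct ancestral
    states under maximum-likelihood Brownian motion on calibrated trees.
    A synthetic generator produces layered, eggshell-like orientation maps
    with known ground truth so that every pipeline stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    ape,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'eggshellEBSD-package.R'
    'quaternions.R'
    'symmetry.R'
    'orientation-map.R'
    'grain-analysis.R'
    'texture-stats.R'
    'phylo-models.R'
    'phylo-asr.R'
    'synthetic-map.R'
    'trait-simulation.R'
    'pipeline-io.R'
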