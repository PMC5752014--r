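Package: integrotax
Title: Integrative Species Delimitation from Morphometric, Barcode,
    Phylogenetic and Spatial Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrative taxonomy of poorly differentiated
    species groups. Implements between-group analysis (BGA) of
    standardized morphometric tables with Monte-Carlo permutation
    testing, Kimura two-parameter (K2P) DNA-barcode distances with
    barcoding-gap and identification-threshold analysis, principal
    coordinates with Cailliez correction for patristic and geographic
    distance matrices, RV-coefficient permutation tests and multiple
    co-inertia analysis (MCOA) of the resulting tables, and
    dispersal-extinction-cladogenesis (DEC and DEC+j) likelihood models
    of geographic range evolution with maximum-likelihood fitting,
    ancestral-range marginals and likelihood-ratio testing. A
    synthetic-data generator produces coherent multi-modal datasets
    (tree, sequences, morphometry, coordinates, ranges) with known
    ground truth so every stage of the pipeline can be validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    cluster,
    igraph,
    withr
Config/testthat/edition: 3
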