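Package: chambergrow
Title: Strain-Adaptive Design of Dental-Implant Healing Chambers on Voxel Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows the geometry of a dental-implant healing chamber by
    strain-adaptive bone remodeling on a regular voxel lattice. Builds a
    synthetic voxelized implant-in-bone model, solves linear elasticity with
    trilinear 8-node hexahedral elements, applies a Mechanostat-style
    disuse/physiological/overuse remodeling probability law driven by
    equivalent strain and local stress nonuniformity, and iteratively swaps
    bone and implant elements inside a circumferential-trough design region.
    Every iteration's geometry is a design candidate, evaluated by the volume
    fraction of healthy surrounding bone (400-1500 microstrain) and the
    bone-implant contact area; the best candidate can be exported as VTK or a
    watertight STL suitable for additive manufacturing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    rlang,
    generics,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
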