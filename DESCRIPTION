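Package: tfm3d
Title: Three-Dimensional Traction Force Microscopy Under Finite Strain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recovers the surface tractions exerted by a cell embedded in a
    three-dimensional extracellular matrix from confocal image stacks of
    fluorescent fiducial beads. Provides subpixel 3D bead tracking, automatic
    cell segmentation, voxel-to-tetrahedron meshing, a finite-strain
    Neo-Hookean finite-element engine, and an iterative three-analysis
    inverse solver formulated in an updated-Lagrangian setting with
    logarithmic-strain accumulation across configurations. Includes a fully
    synthetic sphere-in-prism benchmark with known tractions for round-trip
    validation, and synthetic bead-image generators for testing the tracking
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
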