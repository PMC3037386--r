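Package: morphomovie
Title: Reverse-Engineering Tissue Movement Maps from 2D Organ Outlines and Clonal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct hypothetical two-dimensional tissue movement
    maps of a growing organ (the embryonic limb bud) from an hourly sequence of
    boundary outlines. Boundary control splines define boundary displacements
    that are interpolated with Gaussian radial basis functions, propagated into
    the tissue with an edge spring analogy, and linked across stages by
    conservative triangle-interpolation maps. Virtual clonal fate maps with
    finite-volume cell-mixing diffusion are simulated on the resulting
    MorphoMovie structures, scored against experimental clones to select the
    best-matching map, and used to derive growth tensors, progenitor maps and
    growth-versus-regulation decompositions of gene-expression domains.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
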