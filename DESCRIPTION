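Package: geolattice
Title: Continuous Isometry Invariants and Geographic-Style Maps of
    Two-Dimensional Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Complete, continuous classification of two-dimensional lattices
    up to isometry and rigid motion. Implements obtuse-superbase (Selling /
    Delaunay) reduction, root invariants with a chirality sign, projected
    invariants in the quotient triangle, Bravais-class assignment with
    explicit tolerances, and a spherical latitude/longitude map of the
    lattice space. Includes a pipeline that extracts the three
    two-dimensional sublattices of three-dimensional unit cells (e.g. from
    molecular-crystal databases), bins their invariants into quotient-triangle
    and spherical heat maps, and emits figure-style reports, together with
    synthetic generators for all five planar Bravais families.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
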