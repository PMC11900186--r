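Package: junctionmech
Title: Mechanics of Membrane Tubules and Three-Way Tubular Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrained minimization of the Helfrich bending energy on
    triangulated membrane surfaces, in the style of finite-element surface
    evolution, for cylindrical membrane tethers and three-way tubular
    junctions. Supports thermodynamic ensembles built from the conjugate
    pairs (length, force), (area, tension) and (volume, pressure), retrieves
    tension and pressure as Lagrange multipliers of the area and volume
    constraints, and predicts the tension-driven pearling (bulging)
    transition of tubular junctions: continuation sweeps in luminal volume or
    pulling force, detection of the critical stress parameter, master curves
    over excess volume, and recovery of thermodynamic parameters from the
    master curves. Includes closed-form tether and cylinder-stability theory
    used as oracles, an independent axisymmetric profile minimizer, mesh
    builders for cylinders and junctions, isotropic remeshing, and OFF/PLY
    import/export with a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
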