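Package: fretshape
Title: Ab Initio 3D Shape Reconstruction from Two-Color Single-Molecule
    FRET with Exchangeable Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multipoint structural analysis of single molecules by
    two-color FRET with transiently binding dye-labeled probes. Simulates
    competitive donor/acceptor imager exchange kinetics on 2-4 docking sites,
    detects binding events in two-channel intensity traces, fits the per-event
    FRET histogram as a Gaussian mixture with a donor-only zero peak, converts
    peak efficiencies to distances through the Forster model, and reconstructs
    triangle and quadrangle coordinates in 3D by enumerating dissimilar edge
    assignments and minimizing edge-length violation. Includes generalized
    Procrustes alignment and averaging, bootstrap positional uncertainty,
    rigid-body fitting to reference structures, calibration of the Forster
    radius and dye linker length against the B-DNA helix, and a tree-ensemble
    classifier on congruence-invariant shape features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    xgboost,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    optparse
Config/testthat/edition: 3
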