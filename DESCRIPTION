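Package: helixfit
Title: Genuine Helical-Curve Models for Protein and DNA Backbones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models a biomolecular helix as a series of bona fide helical
    curves, one per sliding window of four consecutive backbone guide atoms
    (C-alpha for proteins, P for DNA). For each quadruple it searches a
    discrete (radius, rise) grid around analytic seed parameters, superposes
    candidate curves by SVD (Kabsch), and keeps the curve minimising the
    closest-point RMSD. Per-residue helix scores quantify deviation from the
    standard protein helix; overlapping window curves are averaged into a
    single C0-continuous model curve; helix-center polylines, per-residue
    tables and score-coloured ribbon meshes (OBJ/PLY) are exported.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
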