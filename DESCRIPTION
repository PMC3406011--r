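Package: lvfiber
Title: Left-Ventricular Mechanics with Shear-Induced Myofiber Reorientation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element model of left-ventricular (LV) mechanics on a
    truncated-ellipsoid wall geometry, coupled to a lumped-parameter systemic
    circulation, with an adaptive myofiber-reorientation law in which the
    unloaded fiber direction evolves towards the deformed fiber direction
    corrected for rigid-body rotation.  Supports normal (situs solitus) and
    mirror-image (situs inversus totalis) initial helix-angle fields with a
    configurable apex-to-base transition zone, and computes torsion, phase-wise
    natural myofiber strain and stroke work density over the cardiac cycle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
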