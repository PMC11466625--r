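Package: axisim
Title: Agent-Based Simulation of Vertebrate Body-Axis Elongation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Center-based, overdamped agent simulations of posterior body-axis
    elongation in the vertebrate embryo. A passive axial column (notochord and
    neural tube merged) is flanked by motile presomitic mesoderm (PSM) confined
    by rigid boundaries, with optional progenitor influx at the posterior
    midline and a passive posterior cell cap. The package generates 2D and 3D
    multi-tissue initial layouts, integrates adhesion-repulsion-motility cell
    mechanics, applies in-silico stretch/compression and cell-deletion
    perturbations, and computes the simulated readouts: axis length and
    elongation extent, grid cell-density profiles, boundary pressure along the
    antero-posterior axis, axial pushing force, progenitor-domain lateral flux,
    and convergence-versus-elongation regime classification. Parameter-space
    sweeps over cell-cell repulsion coefficients, phase-transition detection,
    and a shallow neural-network surrogate of sweep outputs are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nnet,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
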