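Package: holetransfer
Title: Kinetics and Trajectory Diagnostics of Hole Transfer in Oxidized DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the solvent-gated kinetics of positive-charge (hole)
    migration between guanine sites in one-electron-oxidized DNA. Builds and
    solves a four-step absorbing master equation (Arrhenius-activated
    resonance, coherent tunneling, solvent relaxation, oxidative damage) by
    exact linear algebra, stiff time propagation, and Gillespie simulation;
    calibrates the tunneling rate against printed damage-yield ratios and
    predicts how those ratios respond to the activation time. Companion
    trajectory statistics quantify the solvent response from site-energy time
    series: replicate averaging, energy-gap autocorrelation and its
    half-period, HOMO-level equalization time, Coulomb site potentials from
    point-charge snapshots, and wavenumber-resolved Fourier spectra. A
    synthetic-trajectory generator emulates the statistical structure of
    MD/QM-MM output so the full pipeline is testable without external
    simulation software.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
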