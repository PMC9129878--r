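Package: permeon
Title: Ion Permeation Free Energies, Selectivity and Conductance for Narrow Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis machinery for studying ion permeation and selectivity in
    narrow membrane channels such as TMEM175. Implements soft-minimum ion
    proximity collective variables and multiple-walker metadynamics bias
    bookkeeping (hill deposition with boundary images, height schedules,
    time-averaged effective bias), post-hoc reweighting of biased trajectories
    into occupancy and free-energy profiles along the pore axis, smooth
    hydration-shell coordination counting, finite-difference linearized Poisson
    continuum electrostatics for ion-protein interaction energies, conversion
    of a potential of mean force into a single-channel conductance, free-energy
    perturbation analysis with forward/backward hysteresis, and bi-ionic
    patch-clamp analysis (reversal potentials, permeability ratios, IC50
    dose-response fits). A Brownian-dynamics toy-pore simulator with analytic
    ground truth makes every stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
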