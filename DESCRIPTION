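Package: gradnav
Title: Gradient-Based Navigation of Potential Energy Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Enhanced exploration of low-dimensional potential energy
    surfaces without bias potentials. Short, unbiased Langevin dynamics
    segments are restarted from points displaced along the negative
    gradient of the observation density, so the simulation is pushed out
    of already-explored regions while every segment retains the original
    physics. Includes the Mueller and modified Mueller model surfaces
    with analytic gradients and minima search, a compiled Langevin
    integrator with reproducible counter-based noise, escape-time (DWEF)
    and initialization-sensitivity (SSIR) metrics, Boltzmann-inversion
    reconstruction of energy profiles from trajectory histograms, and a
    replay engine that drives the navigation over banks of pre-computed
    collective-variable trajectories.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
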