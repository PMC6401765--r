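Package: nanopost
Title: Coarse-Grained Dynamics of Polymers Confined in Nanopost Arrays
Version: 0.1.0
Authors@R: person("Nanopost", "Developers", role = c("aut", "cre"),
    email = "nanopost@example.org")
Description: Simulation and analysis of coarse-grained bead-spring polymers
    (flexible, semi-flexible and flexible/semi-flexible diblock chains)
    confined in a square-lattice array of parallel nanoposts. Implements the
    WCA excluded-volume, FENE bond, discretized wormlike-chain bending and
    bead-post potentials in reduced Lennard-Jones units, an NVT leap-frog
    integrator with Langevin and Nose-Hoover thermostats, conformational
    observables (axial span, radius-of-gyration anisotropy, interstitial
    occupation number, single-chain structure factor, persistence length),
    and confinement free-energy theory (Odijk and de Gennes regimes)
    predicting the single-to-multiple-occupancy penetration transition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
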