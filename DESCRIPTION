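Package: pentadpd
Title: Dissipative Particle Dynamics of Pentablock Terpolymer Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Mesoscale simulation and analysis of amphiphilic CBABC pentablock
    terpolymers in explicit solvent. Provides a dissipative particle dynamics
    (DPD) engine with the Groot-Warren pairwise thermostat and modified
    velocity-Verlet integrator, harmonic bonds, cell-list neighbour search,
    Lees-Edwards bulk shear at constant strain rate, seeded system builders,
    and synthetic aggregate fixtures (planar bilayer, unilamellar vesicle,
    onion-like vesicle) with known ground truth. The analysis stack covers
    aggregate clustering, radial composition profiles, morphology
    classification, solvent-cargo encapsulation and release time series,
    hydrophilic-bead connectivity, and membrane thickness measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
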