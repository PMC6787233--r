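Package: excitube
Title: Exciton Transport and Annihilation on Double-Walled Molecular
    Nanotubes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic Monte Carlo simulation of exciton hopping, inter-layer
    transfer and exciton-exciton annihilation on periodic molecular grids
    wrapped on cylinders, as realised by double-walled J-aggregate
    nanotubes. Converts labelled exciton trajectories into the observables
    of exciton-exciton-interaction 2D spectroscopy (absorptive and EEI
    transients of diagonal and cross peaks), estimates diffusion constants
    from mean-square displacements, computes inter-layer transfer
    efficiencies, evaluates the Haken-Strobl-Reineker diffusion tensor of a
    Frenkel-exciton Hamiltonian with extended-dipole couplings, and fits
    fluence series globally with two free physics parameters. Includes a
    synthetic-data generator so every stage is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
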