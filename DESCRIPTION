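Package: dispermd
Title: Desk-Scale Molecular Dynamics Screening of Drug-Polymer Solid Dispersions
Version: 0.1.0
Authors@R:
    person("Dispersion", "Modelling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A minimal, fully tested molecular-dynamics toolkit for screening
    active pharmaceutical ingredient (API) and polymeric excipient pairs for
    amorphous solid dispersions. Provides an OPLS-style force field (Lennard-
    Jones + Coulomb with geometric combining rules and 1-4 scaling), steepest-
    descent minimization, a leap-frog integrator with stochastic velocity-
    rescale thermostatting and weak-coupling barostatting, and the analysis
    statistics used in miscibility screening: group-group interaction energies
    (electrostatic, Lennard-Jones, total), the API-polymer/API-API energy
    ratio, geometric hydrogen-bond detection, radial distribution functions,
    mean-squared displacement, and crystal density/lattice validation.
    Includes a synthetic-system generator (toy API archetypes, 10-monomer
    polymer chains, mixture boxes at prescribed weight percent, crystal
    supercells) plus readers and writers for PDB, GRO, XYZ and a documented
    binary trajectory format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
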