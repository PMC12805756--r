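Package: ruggedevo
Title: Stochastic Evolutionary Dynamics on Rugged Fitness Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates evolutionary trajectories of lineages as stochastic
    differential equations on smooth and non-Lipschitz (Holder-continuous)
    fitness landscapes. Provides canonical drift families (quadratic basin,
    fractional-exponent cusp, tilted double well, non-gradient limit cycle),
    an Euler-Maruyama integrator with event detection (escape, absorption,
    divergence), replicate ensembles with an analytic Boltzmann
    stationary-density oracle, local Holder-exponent and Lipschitz-constant
    estimation of drift fields, bifurcation sweeps with tipping-point
    location, and clade-level extensions: watershed-triggered lineage
    branching, disparity-diversity scaling, heavy-tail analysis of
    mutational effect distributions, and Newick tree export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
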