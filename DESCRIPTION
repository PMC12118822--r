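Package: smcsim
Title: Simulation and Analysis of SMC-Driven Mitotic Chromosome Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for studying how condensin and cohesin
    complexes fold mitotic chromosomes. Provides a stochastic 1D lattice
    engine for loop-extruding and diffusing SMC complexes with configurable
    collision rules (stall, bypass, push, unload), CTCF barrier capture and
    turnover; a coarse-grained bead-spring polymer engine (overdamped
    Langevin reference integrator with soft-core repulsion, confinement
    walls and helical restraints); builders for mitotic chromatid models
    with consecutive, nested or overlapping loop arrays and derived
    cylinder/helix geometry; in-silico Hi-C via Gaussian-perturbation
    contact sampling with log-binned P(s) curves, derivative-based
    loop-size and helix-period detectors and a model-fit RMS metric;
    feature scores for binned contact matrices (compartment eigenvector
    and saddle strength, dot pileups, insulation/TAD analysis);
    closed-form extrusion speed and stoichiometry estimators; and
    synthetic fluorescence profiles of simulated sister chromatids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
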