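Package: allelopop
Title: Stochastic Population-Balance Simulation of Allelically Regulated
    Gene Expression in Stem Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale stochastic simulation of a gene expressed under
    allelic (per-chromosome-copy) on/off control in a proliferating stem
    cell population, modelled on Nanog in mouse embryonic stem cells. A
    four-state Markov chain of allelic activity patterns, built from
    observed subpopulation fractions by detailed balance, is coupled to
    per-allele protein production/degradation dynamics (closed-form ODE or
    Euler-Maruyama SDE) and embedded in a kinetic Monte Carlo solver of the
    population balance equations with exponential single-cell growth,
    size-dependent division hazard, symmetric-beta partitioning of
    molecular content at mitosis, and constant-volume/constant-number
    population control. Scenario drivers reproduce in-silico experiments:
    population reconstitution from uniform starting states, multimodal
    protein distributions, knock-in reporter fidelity under half-life
    mismatch and single-allele insertion, transcriptional shutoff, and
    single-allele knockout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
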