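Package: fluxsel
Title: Forward-Time Mutation-Selection Simulation of Metabolic Pathway
    Evolution over a Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the evolution of kinetic metabolic models along a
    rooted phylogeny under a mutation-selection-drift regime.  Kinetic
    parameters mutate with Poisson-distributed proposal counts and
    normally distributed multiplicative effects, reversible reactions are
    kept thermodynamically consistent through Haldane's relationship,
    population fitness is a weighted geometric mean of logistic scores of
    steady-state fluxes under selection, and fixation follows Kimura's
    diffusion approximation.  Includes a self-contained steady-state
    solver for ODE-based kinetic models (stiff integration plus Newton
    refinement), readers for a plain-text native model format and an SBML
    subset, root-population equilibration with windowed stability
    detection, branch-length calibration to generation counts, recursive
    branch simulation with per-branch population sizes, and tabular
    reporting of mutations, trajectories and percent-change matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    deSolve,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
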