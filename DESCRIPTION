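Package: chasekin
Title: Kinetics of Two-Step Mitochondrial Presequence Processing from
    Cycloheximide-Chase Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form and matrix-exponential solutions of sequential and
    branched first-order cleavage/degradation networks (precursor -> A-form ->
    B-form -> degraded), bounded nonlinear least-squares estimation of rate
    constants from cycloheximide-chase band-intensity time courses, half-life
    derivation, and information-criterion discrimination between the
    sequential and branched processing models.  Includes a seeded synthetic
    densitometry generator with named scenarios for wild-type and protease
    mutant strains, parameter-recovery and model-selection simulation
    experiments, tab/comma table input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
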