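Package: hgtflow
Title: Multi-Mechanism Horizontal Gene Transfer Dynamics in Microbial
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action simulation of plasmid spread through a multispecies
    bacterial community by four horizontal gene transfer mechanisms
    (conjugation, natural transformation, phage-mediated transduction and
    extracellular-vesicle-mediated transfer), each with a maximal rate
    constant and a stochastic donor-recipient compatibility matrix.
    Includes the vector end-point estimator used to calibrate per-vector
    rate constants from batch transfer experiments, generators for the
    four compatibility-matrix rulesets (including modular-nested
    phage-host networks), a deterministic Euler/replicator stepper with
    full-spread detection, and an experiment harness for replicated
    mechanism-knockout scenarios and rate-constant sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
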