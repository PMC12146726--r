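Package: revsim
Title: Reversible Molecular Simulation for Force-Field Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Differentiable molecular dynamics by reverse-time simulation.
    Runs the Langevin middle integrator forwards over small periodic systems,
    then steps it backwards with per-step noise replay and accumulation
    vectors to obtain exact gradients of trajectory-derived loss functions
    (enthalpy of vapourisation, radial distribution function match, diffusion
    coefficient) with respect to classical force-field parameters, at
    effectively constant memory cost. Includes Lennard-Jones, double
    exponential, Buckingham and Lennard-Jones soft-core pair potentials with
    reaction-field electrostatics, an ensemble-reweighting gradient baseline,
    an Adam training loop on scaled parameters, synthetic system generators
    and independent gradient oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
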