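Package: quorumsim
Title: Diffusion-Based Quorum-Sensing Feasibility and Dynamics Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state reaction-diffusion model of autoinducer accumulation
    in a spherical bacterial colony, with threshold-based quorum-sensing
    feasibility verdicts, minimum biofilm thickness solving by bisection,
    single-parameter sweeps, and a Monod-kinetics chemostat growth model
    coupled to the diffusion solution for time-dependent autoinducer
    production curves. Includes packaged scenarios and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
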