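Package: mtsm
Title: Markov-Type State Models for Non-Markovian Macrostate Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimators for macrostate transition matrices of molecular
    kinetics when the usual time-scale separation behind a Markov state
    model (MSM) is questionable. Implements the local-equilibrium lumping,
    the Hummer-Szabo optimal projection, a microstate-based projection that
    reproduces macrostate populations exactly, a quasi-MSM scheme that
    extracts the discretized memory kernel of the generalized master
    equation from short-time transition matrices and propagates them to
    long times, and a hybrid propagator combining directly counted
    transition matrices at short times with MSM powers beyond. Includes
    transition counting and trajectory handling for discrete state
    trajectories, a four-well analytic toy model with closed-form implied
    timescales, a seeded Markov-chain sampler, Chapman-Kolmogorov
    diagnostics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
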