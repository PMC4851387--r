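Package: qstoggle
Title: Quorum-Coupled Genetic Toggle Switch Populations
Version: 0.1.0
Authors@R:
    person("Ilya", "Petrov", email = "ilya.petrov@example.org", role = c("aut", "cre"))
Description: Deterministic analysis of populations of genetic toggle switches
    coupled through quorum-sensing autoinducers. Implements the symmetric (S,
    two quorum-sensing arms) and asymmetric (A, one arm) population ODE models
    with analytic Jacobians, signed species-influence graphs with orthant
    monotonicity and strong-connectivity verdicts, Kamke order-preservation and
    monotone parametric-shift harnesses, Newton-based equilibrium finding and
    classification, single-toggle bistability region scans, N-independent
    spectrum reductions for homogeneous and mixed populations, one-parameter
    pseudo-arclength continuation with fold and branch-point detection and
    branch switching, and seeded flip/self-correction ("majority-vote")
    experiments, plus a command-line pipeline interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    numDeriv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
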