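Package: spanlearn
Title: Time-Evolving Psychometric Models of Learning in Visual Working-Memory Span Tasks
Version: 0.1.0
Authors@R: person("Span", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing learning in visual working-memory
    span tasks. Per-item accuracy is modelled with a Weibull (Quick) psychometric
    function of memory set size whose 50%-accuracy threshold evolves as an
    exponential function of trial number; thresholds, learning rates and
    asymptotes are estimated hierarchically across participants and
    between-subject stimulus-response mapping conditions. Includes a seeded
    synthetic span-task generator mirroring a 4-block x 30-trial design with set
    sizes 2-6 and six rotated stimuli mapped to six response buttons, a
    capacity-based participant exclusion filter built on static
    maximum-likelihood Weibull fits, an adaptive Hamiltonian Monte Carlo sampler
    with a fast Laplace approximation mode, convergence diagnostics
    (split R-hat, tail effective sample size), posterior contrast batteries with
    a 95% credible-interval reliability rule, and reduced-model comparison via
    Pareto-smoothed importance-sampling leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
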