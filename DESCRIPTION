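Package: forgetsim
Title: Normative Simulation of Forgetting as Optimal Decision Making in a
    Changing Environment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and decision-policy library for a normative account of
    forgetting in classical conditioning. An agent holds Bayesian beliefs over
    a hidden Markov reward environment in which a stimulus switches between
    being rewarding, neutral and punishing, and chooses between approaching
    and avoiding under stochastic, exponentially distributed costs of
    responding. The package provides the belief filter, greedy
    (immediate-reward) and provident (reward-rate maximizing) policies via
    finite-horizon dynamic programming with analytically integrated Laplace
    cost differences and via average-reward linear programming on a quantized
    belief/cost space, a mechanistic two-synapse approximation with fitting
    routines, and experiment harnesses that produce forgetting curves for
    single, spaced, massed and reversal conditioning protocols, including an
    extended environment with a hidden slow/fast volatility mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    jsonlite,
    yaml,
    optparse,
    lhs
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
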