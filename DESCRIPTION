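Package: nestedaif
Title: Individual and Group-Level Active Inference Agents on Multi-Armed Bandits
Version: 0.1.0
Authors@R: person("nestedaif", "developers", role = c("aut", "cre"),
    email = "nestedaif@example.org")
Description: Discrete-state active inference agents (POMDP generative models
    with expected-free-energy policy selection and two-stage softmax action
    selection) interacting with a three-armed bandit, composed into a
    group-level agent with an explicit Markov blanket (sensory copier,
    internal voters, aggregating active agent). Provides Bayesian (MCMC)
    recovery of the group agent's action precision from its blanket states,
    a parameter-recovery study, and four simulation experiments relating
    individual and emergent group-level generative models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
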