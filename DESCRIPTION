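Package: effsyn
Title: Energy-Efficient Stochastic Synapses in Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the energetic cost of reliable synaptic transmission and
    its consequences for learned patterns of synaptic variability. Implements
    the binomial quantal-release model of postsynaptic potentials, four
    biophysical reliability-cost mechanisms with their power-law scalings,
    feedforward rate networks with trainable Gaussian stochastic synapses
    (reparameterised mean and variance), joint optimisation of synaptic means
    and noise under a performance + magnitude + reliability objective,
    post-training diagnostics linking optimised variability to synapse
    importance (empirical Fisher), and the analytic and empirical comparison
    with variational and Laplace Bayesian posteriors over weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
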