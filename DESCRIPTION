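Package: spinedrift
Title: Reflecting Random-Walk Models of Synaptic Spine Dynamics and Memory Consolidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling long-term memory as an ensemble of neural
    connections whose strengths follow a discrete-time random walk with
    reflecting boundaries. Constructs detailed-balance transition matrices
    from an equilibrium spine-strength distribution and per-state plasticity
    factors, and provides exact analyses (stationarity, state lifetimes,
    fundamental matrix, first-passage times, asymptotic occupancy variances,
    spectral forgetting rates) alongside Monte-Carlo simulation of connection
    ensembles. A simple associative-memory layer (stabilisation learning rule,
    state weights, feedforward inhibition, threshold retrieval) links chain
    dynamics to recall, and experiment drivers reproduce emergent memory laws:
    exponential learning curves, power-then-exponential forgetting, Jost's
    laws, the spacing effect, and Ribot gradients under diffuse lesioning.
    Includes least-squares fitting of the model to two-group retention data
    via relative retrograde gradients, and a synthetic retention-data
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
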