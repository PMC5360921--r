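Package: elevnet
Title: Elevational Gradients in Quantitative Bipartite Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds per-elevation quantitative bipartite interaction networks
    from plant-census tables and analyses how their structure changes along an
    elevational gradient. Computes network-level metrics from first principles
    (connectance, weighted generality and vulnerability, the H2' specialization
    index with marginal-constrained entropy extrema, and Barber's bipartite
    modularity with a seeded label-propagation optimizer), separates abundance
    effects from genuine network reorganization with rarefaction-based 95%
    prediction bands, tests specialization against marginal-preserving
    Monte Carlo nulls, and fits elevational trends by AIC-selected polynomial
    regression and a permutation-based Hoeffding's D test. Includes a synthetic
    community generator emulating an ant-plant census along a tropical
    mountainside, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
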