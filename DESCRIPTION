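Package: sirsnet
Title: Degree-Based SIRS Dynamics of Disturbance Spread on Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Degree-block (annealed mean-field) SIRS model with proportional
    immigration and emigration for the spread of ecological disturbance on
    food-web networks. Computes the basic reproduction number and the critical
    transmission probability from the degree moments, solves the endemic
    self-consistency equation, integrates the per-degree-class dynamics,
    classifies stability of the disturbance-free state, compares uniform,
    targeted and active species-protection ("immunization") strategies under a
    matched protection budget, and cross-checks the mean-field predictions
    against a stochastic discrete-time simulator on explicit networks.
    Includes degree-distribution utilities: edge-list ingestion, moments,
    inverse-degree (a/k) fitting, and a configuration-model generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
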