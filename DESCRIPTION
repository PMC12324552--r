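Package: stapaw
Title: State-Dependent Pirouette-and-Weathervane Models of Chemotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modeling sensory-guided navigation in crawling animals
    such as the nematode C. elegans. Implements an input-driven hidden-state
    model (staPAW) in which two latent behavioral states -- one enriched for
    steering, one enriched for turning -- emit heading-change and speed
    kinematics through state-dependent mixtures of turn and weathervane
    strategies, with state transitions driven by the history of experienced
    concentration. Provides trajectory preprocessing and sensory-feature
    extraction, forward-backward decoding and expectation-maximization
    fitting with cross-validated model comparison, a closed-loop generative
    simulator over analytic concentration landscapes, descriptive behavioral
    statistics (turn detection, inter-turn intervals, pirouette
    identification, bearing analyses, chemotaxis index), a data-constrained
    policy-gradient navigation agent, and a minimal mutual-inhibition rate
    circuit model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
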