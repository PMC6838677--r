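Package: offloadr
Title: Hierarchical Bayesian Modeling of Cognitive Offloading and Metamemory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for simulating and modeling a word-pair learning task in
    which participants may offload memory by saving items to a computer and
    later asking for help (a two-letter hint) at a point cost. Implements a
    generative task simulator, three families of hierarchical Bayesian
    choice-and-recall models (constant, positive-slope and negative-slope
    couplings between subjective hint benefit and latent recall probability),
    factorial model comparison by the deviance information criterion with
    Gelman-Rubin convergence screening, posterior predictive checks, a
    confidence-rating model, brute-force grid posteriors for validation, and
    individual-difference analyses including bootstrap mediation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
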