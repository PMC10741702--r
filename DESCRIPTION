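Package: competitron
Title: Competitive Perceptrons with Intrinsic Plasticity, Metaplasticity and Lateral Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Rate-coding artificial neurons with bio-inspired homeostatic
    properties: a shifted-sigmoid activation whose threshold adapts to past
    activity (intrinsic plasticity), a presynaptic (Grossberg-type) learning
    rule whose weights converge to conditional firing probabilities, artificial
    metaplasticity as a pattern-frequency-dependent learning rate, and lateral
    inhibition producing winner-take-all competition. These are assembled into
    the Competitive Perceptron, a single-layer network with normalized inputs
    that escapes linear separability (demonstrated on XOR), and a simplified
    koniocortex-like network with thalamocortical preprocessing and shunting
    normalization. Includes seeded synthetic data generators, JSON/CSV model
    and trace serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
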