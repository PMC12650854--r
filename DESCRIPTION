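Package: lpbn
Title: Learning Probabilistic Boolean Networks by Structural Policy Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trainable probabilistic Boolean networks for tabular learning,
    reinforcement learning, and gene-regulatory dynamics. Each Boolean unit
    holds a categorical policy over two input bits and a two-input logical
    operator; structure is learned with variance-reduced score-function
    (REINFORCE) gradients while a linear, logistic, softmax, or policy head is
    trained by ordinary gradients. Includes a one-hot binarization substrate
    for real-valued features, parameter-matched multilayer-perceptron
    baselines, LineWorld and cart-pole control environments, synchronous
    Boolean network dynamics with attractor enumeration and stationary
    analysis of the perturbed Markov chain, rule extraction with coverage and
    precision, and a paired nonparametric benchmark harness (exact sign test,
    bootstrap confidence intervals, Holm correction, equivalence testing,
    Cliff's delta). Ships a ten-gene mammalian cell-cycle Boolean network as a
    worked case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
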