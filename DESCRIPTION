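Package: sfanet
Title: Recurrent Spiking Networks with Spike-Frequency Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and surrogate-gradient training of recurrent networks of
    leaky integrate-and-fire neurons whose firing threshold adapts to their own
    spiking (spike-frequency adaptation, the GLIF2 mechanism), together with the
    dual enhanced-excitability model (ELIF) and Tsodyks-Markram short-term
    synaptic plasticity. Includes procedural generators for temporal-computing
    tasks (STORE-RECALL working memory in 1 and 20 dimensions, the 12AX
    continuous-performance task, duplication/reversal of symbol strings, and a
    threshold-crossing spike encoder for sequential MNIST), backpropagation
    through time with a dampened pseudo-derivative for the spike
    non-linearity, and analyses of the emergent neural code: a hand-wired
    negative-imprinting demonstration, cross-period SVM decoding of memory
    content, three-way ANOVA neuron categorisation with omega-squared effect
    sizes, and peak-activity sorting.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
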