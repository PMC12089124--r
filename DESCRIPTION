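Package: plastisim
Title: Bipartite Synaptic-Network Simulation of Learning in Young and
    Ageing Brains
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates memory formation on a bipartite synaptic network
    with two biologically inspired weight-update rules: multiplicative
    strengthening in the style of long-term potentiation (LTP) for young
    learning, and conservative edge rewiring in the style of
    multi-innervated dendritic spines (MIS) for old learning. Provides
    exhaustive enumeration of k-of-N binary input patterns, empirical
    calibration of the output firing threshold, fitness-proportionate
    (roulette-wheel) node and edge selection, seeded cohort experiments
    over the full valid-pattern space (including learning from weights
    preloaded by prior young learning), and analyses of learning speed,
    output-pattern similarity, memory specificity, per-node activation
    probability and cohort overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
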