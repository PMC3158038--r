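Package: ssanet
Title: Spiking-Network Simulation of Stimulus-Specific Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Clock-driven simulation of small spiking networks that exhibit
    stimulus-specific adaptation (SSA) through convergent short-term
    depressing synapses. Provides adaptive exponential integrate-and-fire
    (AdEx) units driven by frequency-tuned Poisson inputs, three-state
    (recovered/effective/inactive) kinetic synapses with depression,
    Ornstein-Uhlenbeck background conductance noise, generators for oddball,
    two-state Markov, block/sequential/random and many-standards tone
    protocols, and analysis tools for SSA indices, peri-stimulus time
    histograms, history-conditioned responses and the associated hypothesis
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
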