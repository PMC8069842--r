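Package: ppcoevo
Title: Co-Evolving Predator-Prey Gridworld Ecosystems with Multi-Agent
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of a predator-prey ecosystem on a
    toroidal lattice, where both species are controlled by shared stochastic
    neural-network policies conditioned on partial egocentric observations.
    Policies co-evolve by iterated approximate best responses trained
    off-policy with an f-divergence-regularized primal objective
    (AlgaeDICE-style) and entropy-regularized policy gradients.  Includes a
    deep-Q-learning baseline, an experiment suite for population dynamics
    (oscillations, phase-plane cycles, swarming via the Clark-Evans index,
    robustness sweeps), reproducible seeded runs, and CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
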