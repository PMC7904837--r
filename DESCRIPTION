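Package: dynmi
Title: Dynamical Mutual Information from Single-Cell Signaling Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the mutual information that accumulates over time between
    stimulus conditions and ensembles of single-cell signaling response trajectories.
    Per-condition stochastic models (time-inhomogeneous Markov chains or hidden Markov
    models fitted by Baum-Welch) supply trajectory probabilities via the forward
    algorithm; the dynamical mutual information (dMI) between stimulus identity and
    cumulative response trajectories is then maximized over the stimulus-weight
    distribution on the probability simplex. Includes model-quality metrics (relative
    Kullback-Leibler divergence, false k-nearest-neighbor mixing probability, rescaled
    held-out log-likelihood), a split-half protocol for detecting overfitting,
    timepoint-permutation controls, a single-timepoint mutual-information baseline,
    and seeded generators for synthetic hidden-Markov and oscillatory trajectory
    ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
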