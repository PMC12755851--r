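Package: ephysclust
Title: Input-Driven Classification of Neuronal Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for input-dependent functional
    classification of neurons from somatic current-clamp recordings. Generates
    step-and-hold and frozen-noise (Markov-modulated Poisson population)
    stimulation currents, simulates and fits generalized leaky integrate-and-fire
    (GLIF) neurons with spike-triggered adaptation currents and a moving
    threshold, extracts action-potential, passive-biophysical, adaptation-current
    and spike-triggered-average attribute sets, clusters each attribute set on a
    fuzzy k-nearest-neighbour graph with Louvain community detection (including
    modularity-based resolution/stability selection and ensemble-consensus
    clustering), quantifies cross-protocol and cross-attribute agreement
    (likelihood matrices, adjusted Rand index, adjusted mutual information,
    cosine-similarity summaries), and decomposes shared versus private variance
    across attribute sets with multi-set correlation and factor analysis (MCFA).
    A synthetic ground-truth population generator makes every stage testable
    without experimental recordings.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
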