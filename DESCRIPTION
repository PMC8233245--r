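Package: caim
Title: Causal Inference for Microcircuits from Neural Ensemble Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs causal networks among clusters of neurons from binary
    event time series (spike trains or calcium transient events). Neurons are
    grouped by nearest-neighbour graph construction and walktrap community
    detection, binary cluster-state trajectories are inferred by thresholded
    voting, and a weighted directed two-slice temporal Bayesian network over
    cluster states is learned from tree-ensemble variable importances. Includes
    a ground-truth dynamic Bayesian network simulator with flip-noise neuron
    generation, a noisy integrate-and-fire microcircuit simulator, and the
    evaluation metrics (Rand index, silhouette score, edge-recovery AUC) needed
    to validate every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    cluster,
    igraph,
    randomForest,
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
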