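Package: workloadnet
Title: Band-Resolved Functional Brain Networks and Graph-Attention
    Classification of EEG Cognitive Workload
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for task-independent cognitive-workload analysis of
    multichannel EEG. Builds band-resolved functional brain networks from
    phase-locking value, phase-lag index, Pearson correlation or mutual
    information, with power-spectral-density and differential-entropy node
    features; computes small-world, clustering, path-length and efficiency
    graph metrics with degree-preserving surrogate nulls and per-node
    ANOVA statistics; and classifies workload levels with a stacked
    graph-attention + convolution network (SGATCN) over the four-band
    discrete graph, evaluated by leave-one-task-out cross-validation.
    Includes a protocol-faithful synthetic-EEG generator with known
    band-specific phase coupling for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
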