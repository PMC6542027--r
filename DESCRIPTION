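Package: syllableseq
Title: Unsupervised Discovery of Behavioral Syllables from Depth Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Segments depth-video recordings of a freely behaving rodent into
    a sequence of discrete behavioral syllables (brief, reused pose-dynamics
    motifs) and their transition grammar. Pose extraction produces
    egocentrically aligned height frames from overhead depth video; PCA or
    random projection compresses them into a low-dimensional pose series; a
    sticky hierarchical-Dirichlet-process autoregressive hidden Markov model,
    fit by Gibbs sampling in a weak-limit truncation, assigns every frame a
    syllable label. Downstream analytics compute syllable usages, durations,
    transition matrices and state-map graphs, and compare conditions with
    permutation tests under false-discovery-rate control. A synthetic module
    generates ground-truth-known pose trajectories and rendered depth videos
    for validation, including module-free control data and held-out
    model-comparison baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    mclust,
    tiff,
    yaml,
    jsonlite,
    igraph,
    readr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
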