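Package: cerenet
Title: Graph-Theoretic Analysis of Cerebellar Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for group studies of the cerebellar functional
    connectome from regional resting-state fMRI time series. Covers
    time-series-level preprocessing (framewise displacement with
    rotation-to-arc-length conversion on a 50 mm sphere, motion-based
    exclusion, joint nuisance regression and 0.01-0.08 Hz band-pass
    filtering in a single linear model), Pearson connectivity, sparsity
    thresholding over a 0.12-0.40 grid with a minimum-spanning-tree
    backbone, weighted graph metrics (Onnela clustering coefficient,
    characteristic path length, nodal degree and betweenness centrality)
    normalized against Maslov-Sneppen degree-preserving random networks,
    area-under-curve summaries across sparsity, nonparametric permutation
    tests with false-discovery-rate control, and covariate-adjusted
    partial correlations with clinical scores. Includes a synthetic-cohort
    generator producing BOLD-like multivariate series with tunable
    modular correlation structure for validation and power experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    MASS,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
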