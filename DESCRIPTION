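Package: dynmod
Title: Temporal Dynamics of Modular Brain Network Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the temporal stability of modular organization
    in functional brain networks. From parcellated resting-state time series,
    the package builds tapered sliding-window Fisher-z weighted connectivity
    matrices, detects communities by multi-restart Louvain modularity
    maximization on signed weighted graphs across a grid of resolution
    parameters, selects each subject's resolution by mutual-information
    agreement with a canonical network reference, quantifies temporal
    variability as the standard deviation of window-wise modularity, detects
    extreme-modularity states under individual and group threshold
    conventions, computes coclassification (module allegiance) stability
    matrices with network-level aggregation, and relates all measures to a
    phenotype through partial Spearman correlations with nuisance covariates.
    A seedable synthetic-cohort generator with planted time-varying modular
    structure makes every stage testable without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
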