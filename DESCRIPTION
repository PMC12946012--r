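Package: pairephys
Title: Paired Patch-Clamp Recording Analysis and Interneuron Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of intracellular electrophysiology for
    studies of neuromodulation at cortical pyramidal-cell to interneuron
    synapses. Provides a synthetic generator for current-step and paired
    whole-cell recordings (adaptive integrate-and-fire neurons with stylized
    spikes and a sag conductance; binomial multi-site quantal release with
    short-term plasticity), extraction of passive and action-potential
    features, UMAP plus k-means classification of fast-spiking versus
    non-fast-spiking interneurons, per-connection EPSC, paired-pulse-ratio and
    failure-rate quantification with nonparametric modulation categorization,
    intrinsic-property (holding current, input resistance) analysis, and
    predictor correlations, organised as a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr,
    yaml
Config/testthat/edition: 3
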