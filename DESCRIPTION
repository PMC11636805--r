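Package: causalflow
Title: Causal Flow Inference and Interventional Connectivity for Neural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers directed functional connectivity ("causal flow") between
    simultaneously recorded units from resting multivariate time series using
    convergent cross-mapping on Takens delay embeddings, with twin-surrogate
    significance testing, and quantifies perturbation effects as interventional
    connectivity (Kolmogorov-Smirnov statistics between pre- and
    post-stimulation activity distributions). Includes a ground-truth network
    simulator (a chaotic Rossler driver feeding a recurrent rate network) with
    controlled private/shared noise and pulse-perturbation protocols,
    information-theoretic baselines (univariate, multivariate, extended and
    radial-basis-function Granger causality, transfer entropy), and evaluation
    tools (Gini coefficients, spatial footprints, distance residualization,
    causal-flow versus interventional-connectivity prediction tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
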