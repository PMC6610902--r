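Package: gliacap
Title: Channel Capacity of Noisy Glioma Differentiation Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Information-theoretic analysis of stochastic signaling models of
    cholera-toxin induced glioma differentiation. Simulates ensembles of
    single-cell GFAP trajectories under additive-noise and chemical Langevin
    equation models across a grid of composite signals (CT dose x noise
    level), reduces trajectories to scalar descriptors or multivariate
    response vectors under symmetric, balanced, or greedy time-point
    sampling, and estimates multivariate channel capacities with a k-nearest
    neighbour density estimator maximized over input distributions by a
    Blahut-Arimoto fixed point. Includes subpopulation decompositions
    (terminal-differentiation filtering, k-means trajectory clustering) and
    synthetic fixture channels with known information content for estimator
    validation.
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
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
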