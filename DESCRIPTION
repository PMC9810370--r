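Package: graphbold
Title: Graph Neural Network Forecasting of Brain-Network Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasting of spatiotemporal signals on brain-network graphs.
    Implements three graph-aware forecasters (a diffusion-convolution
    recurrent network, a graph WaveNet with dilated causal convolutions, and
    a causal temporal-attention network) together with three ways of
    defining the spatial coupling between regions (structural adjacency,
    node2vec connectome-embedding similarity, and a learned adaptive
    adjacency), a vector-autoregression baseline, band-pass filtering,
    windowing and evaluation utilities, and a perturbation-based directed
    influence measure. Models are trained with a built-in reverse-mode
    automatic-differentiation engine so the package runs on a plain CPU.
    A synthetic graph-coupled signal generator with known ground truth makes
    every component testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
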