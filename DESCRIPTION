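Package: nmrquant
Title: Neural-Network Quantification of Metabolites from Simulated 1D 1H-NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates realistic one-dimensional proton NMR spectra of complex
    metabolite mixtures (Lorentzian multiplets on a shared chemical-shift grid,
    concentration distributions spanning a high dynamic range, and a data
    augmentation workflow covering noise, exponential line broadening,
    per-analyte chemical-shift jitter, baseline drift, and interference
    singlets) and trains neural networks to quantify metabolite concentrations
    directly from the binned spectra. Ships three architectures (multi-layered
    perceptron, 1-D convolutional network, and encoder-only transformer) with
    hand-derived backpropagation and AdamW optimisation, a battery of
    regression losses for high-dynamic-range targets, MAPE-based evaluation
    with confidence intervals, and a seeded hyperparameter-search harness with
    median and threshold pruning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
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
    yaml,
    pracma,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
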