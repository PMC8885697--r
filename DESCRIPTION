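Package: grinsyn
Title: Functional Classification of GluN2A Variants and Synaptic NMDA Receptor Biophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping NMDA receptor (GluN2A) missense variants and for
    studying their synaptic consequences. Provides a factor-analysis pipeline that
    classifies variants into gain- and loss-of-function groups from six-property
    heterologous-expression measurements (rank-based alternating-least-squares
    imputation, log-ratio normalisation, correlation PCA with varimax or promax
    rotation, elbow-selected k-means, and double-bootstrap-calibrated BCa confidence
    intervals for Kendall's tau-b); offline processing of paired-recording evoked
    EPSCs (series-resistance compensation, stimulus-artifact blanking, Ohm's-law
    conductance conversion, AMPA/NMDA component separation, bi-exponential decay
    fitting with weighted time constants); a reduced compartmental CA1-like neuron
    with two-compartment dendritic spines for simulating charge-matched mutant-like
    NMDA conductances during synaptic trains; and synthetic-data generators with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
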