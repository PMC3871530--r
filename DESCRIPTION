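Package: lrbinet
Title: Gene Regulatory Network Inference from Expression and eQTL
    Genotypes by Bayesian Linear Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers directed gene regulatory networks from paired
    gene-expression and genetic-perturbation (cis-eQTL genotype) data.
    A linear structural equation model Y = BY + FX + E is decomposed
    into one linear regression per gene, and the regulatory coefficients
    are estimated with an iterative Gibbs-style sampler under a
    Normal-Gamma conjugate prior (the LRBI estimator). Includes a
    network and dataset simulator for directed acyclic and cyclic
    networks, a power-of-detection / false-discovery-rate / numerical
    error evaluation harness, tab-separated matrix and edge-list
    readers and writers, SIF export, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
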