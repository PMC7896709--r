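Package: msnnh
Title: Multisite Neutral and Niche-Neutral Hybrid Models for Microbiome
    Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits the multisite neutral (MSN) model of community assembly --
    a hierarchical Dirichlet process approximation to Hubbell's unified
    neutral theory for metacommunities of several local communities with
    site-specific immigration -- by Gibbs sampling, and runs two-level
    posterior-predictive (pseudo-p) neutrality tests at the metacommunity
    and local-community scales.  Also fits a niche-neutral hybrid (NNH)
    model in which each site is a niche whose species abundance
    distribution follows a zero-truncated negative-binomial neutral kernel
    with niche-specific birth/death ratio and immigration, tested by
    chi-squared goodness of fit over Preston octaves.  Includes Hill-number
    and dominance metrics, logistic-regression analysis of pass status with
    subset selection, synthetic multisite community generators (neutral,
    hybrid, and non-neutral controls), and four-way MSN/NNH classification
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
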