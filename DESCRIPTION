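Package: nmalgm
Title: Network Meta-Analysis with Latent Gaussian Models and Nested
    Laplace Approximation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Contrast-based network meta-analysis (NMA) as a generalized
    linear mixed model with an arm-based likelihood for dichotomous,
    continuous, and count endpoints.  Implements the fixed-effect model,
    the consistency model with the Higgins-Whitehead compound-symmetric
    heterogeneity structure, the design-by-treatment interaction model
    with random inconsistency parameters (Jackson model), and a network
    meta-regression extension with a constant covariate-by-treatment
    interaction.  Inference is by a purpose-built nested Laplace
    approximation for latent Gaussian models (Gaussian approximation of
    the latent field, numerically integrated hyperparameter posterior,
    mixture marginals, and DIC), cross-checked by an adaptive
    Metropolis-within-Gibbs sampler.  Includes a simulation module for
    generating arm-level networks from the same models and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
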