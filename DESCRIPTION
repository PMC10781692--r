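Package: specdcm
Title: Spectral Dynamic Causal Modelling of Stimulation-Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring directed (effective) connectivity among
    resting-state fMRI regions of interest with spectral dynamic causal
    modelling, and for carrying subject-level posteriors into hierarchical
    group inference with parametric empirical Bayes, Bayesian model
    reduction and Bayesian model averaging. The package covers the full
    analysis path of an MRI-navigated accelerated theta-burst stimulation
    study: synthetic cohort generation from known coupling matrices through
    a balloon-Windkessel hemodynamic model, temporal preprocessing
    (volume discarding, motion screening, confound regression, bandpass
    filtering, Gaussian smoothing), seed-based functional connectivity
    profiling with individualized target selection against the subgenual
    anterior cingulate, cross-spectral model inversion by Variational
    Laplace, and a clinical outcome layer (percent reductions,
    response/remission classification, longitudinal tests and
    connectivity-outcome correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
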