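Package: nidge
Title: Robust Bayesian Detection of Differential Gene Expression with
    Normal/Independent Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian hierarchical modelling of log-scale gene expression
    for two or more sample groups, with the Gaussian error law replaced by
    the normal/independent (scale-mixture-of-normals) family: normal,
    Student t, slash, contaminated normal and Laplace.  A mixture prior
    over group-mean equality patterns yields per-gene posterior
    probabilities of differential expression; decision rules based on
    Bayesian error rates (bFDR, bFNR, bTNR, bFPR, bTPR) and ROC/AUC
    summaries are provided, together with a Metropolis-within-Gibbs
    sampler, Gelman-Rubin convergence diagnostics, and a simulation-study
    driver for power evaluation under contaminated-normal and heavy-tailed
    error regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
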