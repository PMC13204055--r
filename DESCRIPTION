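Package: mvpheno
Title: Multi-View Factor Analysis and Consensus Phenotyping of Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Data-driven phenotyping of heterogeneous cohort data. Fits a
    multi-view Bayesian factor model (variational inference with automatic
    relevance determination priors, Gaussian and Bernoulli likelihoods,
    native handling of missing entries), removes demographic confounding
    from the latent factor scores by residualization on age, age squared
    and sex, derives participant phenotypes by bootstrap consensus K-means
    with stability-based selection of the number of clusters, characterizes
    the phenotypes by nonparametric effect sizes, and quantifies how well
    the unsupervised labels can be reconstructed from the original features
    with a gradient-boosted classifier. Includes a synthetic multi-view
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
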