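Package: hetconn
Title: Bayesian Multivariate Heteroscedasticity Models for Functional
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Group-difference functional connectivity analysis via two
    Bayesian multivariate heteroscedasticity models: a low-dimensional
    rank-one covariance regression in which the covariance of a
    multivariate parcel timeseries is a function of a design matrix, and
    a full covariance regression in which per-subject scatter matrices
    follow a Wishart distribution whose scale is a linear combination of
    group covariance components with LKJ correlation priors.  Includes
    autocorrelation-based effective-sample-size estimation and thinning,
    posterior-expected false discovery rate control for differential
    correlations, a generative simulator matching both model classes, and
    a repeated-subsampling power analysis with set-matching true positive
    and false discovery metrics.  Posterior inference uses a built-in
    Hamiltonian Monte Carlo sampler with analytic gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests: testthat (>= 3.0.0), MASS, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'hetconn-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'data-io.R'
    'ess.R'
    'hmc.R'
    'lowdim.R'
    'fullcov.R'
    'fdr.R'
    'simulate.R'
    'power.R'
    'cli.R'
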