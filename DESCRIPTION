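Package: providervar
Title: Separating Provider-Level Variation from Binomial Sampling Error
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimators of the between-provider distribution of a binomial
    outcome probability from per-provider event counts. Raw sample
    proportions overstate true provider-level variation because each
    proportion carries binomial sampling error; this package implements and
    compares corrections: the Gaussian hierarchical (random-intercept
    logistic) model with its logit-normal density, empirical-Bayes
    predictions, a semi-parametric Dirichlet-process beta-binomial mixture
    fitted by collapsed Gibbs sampling, the smoothing-by-roughening
    nonparametric empirical-Bayes estimator, and moment-adjusted imputation,
    which minimally displaces the observed proportions so that their first M
    sample moments unbiasedly estimate the moments of the latent probability
    distribution. A simulation engine with exact density, distribution
    function and variance accessors, integrated-squared-error metrics and a
    Monte Carlo study driver support method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    yaml
Config/testthat/edition: 3
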