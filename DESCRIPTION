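Package: obrisk
Title: Optimal Bayesian Risk Classification and Risk Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-class Bayesian classification and risk estimation under
    uncertainty in the feature-label distribution. Implements conjugate
    posterior models (Dirichlet-multinomial for discrete features; five
    Gaussian covariance models based on normal-inverse-Wishart priors),
    closed-form effective and effective-joint predictive densities, Bayesian
    minimum mean-square error risk estimators (BRE), optimal Bayesian risk
    classifiers (OBRC), and the sample-conditioned mean-square error of
    arbitrary risk estimators, with Monte Carlo approximations where closed
    forms are unavailable. Includes classical cross-validation, leave-one-out
    and 0.632-bootstrap risk estimators, plug-in discriminant baselines, and
    a simulation harness for prior-sampled synthetic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
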