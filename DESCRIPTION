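Package: spdeSDM
Title: Bayesian Spatial Species Distribution Modelling via Laplace and SPDE Approximations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bernoulli-logit latent Gaussian species distribution models
    with second-order random-walk covariate smooths and a Matern spatial
    random field represented through the stochastic partial differential
    equation (SPDE) finite-element approximation. Inference uses a nested
    Laplace approximation: a Gaussian approximation to the latent field at
    numerically optimized hyperparameters, with a post-hoc hyperparameter
    grid mixture for posterior marginals. Includes collinearity screening
    (Pearson correlation and generalized variance inflation factors),
    DIC and conditional-predictive-ordinate model selection, forward
    stepwise search, stratified k-fold validation with presence-absence
    metrics (AUC, sensitivity, specificity, Cohen's kappa), posterior
    prediction surfaces on regular grids, and a synthetic observer-bycatch
    data generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    ape,
    car,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
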