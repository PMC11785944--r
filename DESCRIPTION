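Package: sorbfit
Title: Water Sorption Isotherm Modeling and Model Selection
Version: 0.1.0
Authors@R: person("CESURCAFE", "Modeling Group", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits and compares models of water sorption isotherms for dried
    food products: twelve conventional sorption equations (GAB with
    Arrhenius temperature dependence, Peleg, Smith, Kuhn, DLP, Chung-Pfost,
    Caurie, Iglesias & Chirife, White & Eiring, Polynomial, Oswin,
    Yanniotis & Blahovec) with linear temperature parameterization and
    dummy-variable covariates for postharvest method and sorption branch,
    plus four machine-learning regressors (regression tree, random forest,
    k-nearest neighbors, nu-support-vector regression with a Laplacian
    kernel). Parameters are estimated by nonlinear least squares with
    genetic-algorithm or quadratic-rearrangement initialization, with
    asymptotic 95 percent confidence intervals. Models are ranked by a
    repeated random 75/25 train/validation protocol, residual-validity
    screening (Ljung-Box, Brown-Forsythe/Levene) and two-factor ANOVA with
    Fisher LSD letter groups. Includes a synthetic dynamic-dewpoint-isotherm
    generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    quadprog,
    FNN,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
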