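Package: ipdmasim
Title: Simulation Framework for One-Stage and Two-Stage Individual
    Patient Data Meta-Analysis of Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates two-level individual patient data meta-analysis
    (IPD-MA) datasets with a binary outcome and a binary exposure under
    random-study-effects or stratified-study-effects logistic models, and
    compares pooling strategies by Monte-Carlo simulation: the two-stage
    DerSimonian-Laird method-of-moments estimator, a two-stage bivariate
    random-effects meta-analysis fit by restricted maximum likelihood, and
    one-stage logistic generalized linear mixed models (random intercept
    plus random slope, or stratified intercepts plus random slope) fit by
    penalized quasi-likelihood or adaptive Gauss-Hermite quadrature.
    Performance is summarised as bias, root mean squared error, Wald
    coverage and numerical convergence of the pooled log odds ratio and
    the between-study variance of the treatment effect.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    lme4,
    metafor,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
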