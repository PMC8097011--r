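Package: colliderbias
Title: Collider Bias in Regression Models with Polygenic Scores and
    Heritable Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study endogenous selection (collider) bias that
    arises when heritable covariates are included alongside polygenic
    scores in linear regression models. Provides a structural-equation
    simulator for the gene-environment-confounder-outcome system,
    closed-form large-sample expressions for the biased ordinary
    least squares coefficients and the inflation of explained
    variance, additive, gene-by-environment interaction and
    two-stage least squares estimators, a sensitivity calculator that
    attributes observed coefficient attenuation to collider bias, and
    replicated simulation grids over gene-environment correlation and
    confounder strength with tidy outputs and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
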