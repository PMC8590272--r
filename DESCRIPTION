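Package: hetlogit
Title: Heterogeneity Measures for Two-Level Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies between-cluster heterogeneity in two-level logistic
    regression models for clustered binary outcomes. Implements the four
    measures commonly used in multilevel epidemiology -- the latent-variable
    intraclass correlation coefficient (ICC), the median odds ratio (MOR),
    the 80% interval odds ratio (IOR-80) and the sorting-out index (SOI) --
    together with a clustered binary data simulator, a maximum-likelihood
    random-intercept logistic fitter based on adaptive Gauss-Hermite
    quadrature, and a Monte-Carlo study runner that evaluates estimator
    accuracy (average estimates and root mean square errors) over grids of
    cluster counts, cluster sizes and random-effect variances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
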