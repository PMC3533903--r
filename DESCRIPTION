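Package: pcmreg
Title: Latent Regression Partial Credit Models for Multi-Item
    Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for spatio-temporal Rasch analysis of ordinal
    multi-item quality-of-life questionnaires such as the SF-36.
    Implements the Partial Credit Model with pairwise conditional
    estimation of item thresholds, a two-stage differential item
    functioning (DIF) scan based on stratum-wise item locations and
    weighted ANOVA, pseudo-item expansion to absorb detected DIF,
    nonparametric item response theory checks (Loevinger scalability
    coefficients and a monotonicity criterion), item-trait chi-square
    fit tests with sample-size rescaling, and a latent regression mixed
    Partial Credit Model in which covariates explain both the mean and
    the variance of the latent trait, with backward model selection,
    quantitative age recoding, and an explained-variance rate statistic.
    A synthetic-data generator emulating large general-population
    health surveys provides a ground-truth test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
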