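Package: rqrdiag
Title: Randomized Quantile Residual Diagnostics for Count Regression Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood fitting of Poisson, negative binomial (NB),
    zero-inflated Poisson (ZIP) and zero-inflated negative binomial (ZINB)
    regression models with a log link for the count mean and a logit link for
    the structural-zero probability, together with four residual types for
    model diagnosis: Pearson, deviance, middle-point quantile (MQR) and
    randomized quantile residuals (RQR). Provides Shapiro-Wilk-based
    goodness-of-fit testing of residual normality, replicated-RQR p-value
    summaries, normal QQ plots with simulated envelopes, and a simulation
    harness for type-I-error and power studies of residual-based
    goodness-of-fit tests under non-linearity, over-dispersion and
    zero-inflation misspecification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
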