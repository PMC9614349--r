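Package: ihtlm
Title: Informative Hypothesis Testing for Linear Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequentist informative (order-constrained) hypothesis testing
    for the linear regression model. Fits equality- and inequality-constrained
    least-squares models via exact quadratic programming, computes the full
    catalogue of classical and informative test statistics (Wald, likelihood
    ratio, score, F, t, F-bar and the distance statistic) in naive and
    degrees-of-freedom-corrected versions, derives chi-bar-squared and F-bar
    mixture weights from the constraint-cone geometry, and provides a
    Monte-Carlo harness for type-I and type-II error studies.
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
    mvtnorm,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
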