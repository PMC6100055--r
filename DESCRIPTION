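Package: emimpute
Title: Expectation-Maximization Completion of Multivariate Normal
    Property Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of a multivariate normal mean
    vector and covariance matrix from incomplete data by the
    expectation-maximization (EM) algorithm, with the observed-data
    log-likelihood evaluated over missingness-pattern groups, followed by
    single conditional-mean imputation of the missing cells.  Ships a
    variable schema and fixtures for environmental, health and safety
    descriptors of organic solvents (toxicological endpoints,
    biodegradability, bioconcentration), log-transform handling, a
    sentinel rule for non-volatile compounds, post-fit diagnostics
    (principal component analysis, Mardia's multivariate kurtosis test,
    bootstrap standard errors of the fitted means), and a synthetic-data
    generator with study-shaped missingness for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
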