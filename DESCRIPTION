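Package: lookalike
Title: Look-Alike Data Fusion by Multiple Imputation with Chained Equations
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Treats the fusion of two independent person-level datasets as a
    missing-data problem: variables observed only in a donor dataset are
    mass-imputed into a recipient dataset by multiple imputation with chained
    equations over a harmonized comparison vector of shared covariates.
    Includes declarative variable harmonization, a seeded synthetic-population
    generator calibrated to published survey and service-records marginals for
    sexual-violence victim-survivors, a fully-conditional-specification
    imputation engine with proper parameter draws, Rubin's-rules pooling with
    Barnard-Rubin degrees of freedom, validation regressions (OLS, logistic,
    negative binomial with AIC/BIC count-family selection), and three-column
    donor/recipient/synthetic comparison reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
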