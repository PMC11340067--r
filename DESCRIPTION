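Package: countdisp
Title: Count-Data Regression Models for Disease Incidence Disparities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood Poisson, negative-binomial (NB2) and
    generalized Poisson (GP) log-link regressions for over-dispersed
    council-level disease counts, with Wald inference, information-criteria
    model comparison (AIC, AICc, BIC), Pearson chi-square dispersion
    diagnostics, contingency-table association tests, and a seeded synthetic
    council-data generator that emulates the administrative structure of a
    national health-information-system dataset. Includes the generalized
    Poisson probability mass function, moments, support bound and sampler in
    both natural and mean parametrizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
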