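Package: raschkit
Title: Rasch Measurement Analysis for Rehabilitation and Patient-Reported Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the polytomous Rasch model (partial credit and rating scale
    parameterisations) by conditional maximum likelihood and provides the
    measurement-requirement test battery used in rehabilitation outcome
    research: INFIT/OUTFIT homogeneity tests with sample-size-corrected
    critical intervals, class-interval chi-square and ANOVA item fit, person
    fit, local item dependency detection through residual correlations with
    testlet/super-item construction, explained common variance, the
    principal-component/t-test unidimensionality check, differential item
    functioning by two-way ANOVA of residuals with item splitting and the
    anchored substantive-DIF effect-size decision, person separation
    reliability, targeting (Wright map), ordinal-to-interval transformation
    tables, and test equating via total scores. Includes a truth-tagged
    simulator of polytomous response data with controllable violations (local
    dependency, DIF, multidimensionality, off-targeting) and an automated,
    logged analysis protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
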