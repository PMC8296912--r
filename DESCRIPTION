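Package: childineq
Title: Socioeconomic Inequality in Child Health: Concentration Indices,
    Dominance Tests and Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement of wealth-related inequality in binary child-health
    indicators from complex-survey microdata. Derives full-immunization,
    food-insecurity and malnutrition indicators from survey ingredients
    (card-dated vaccine doses, 13 food-group consumption flags,
    weight-for-age z-scores), computes weighted fractional socioeconomic
    ranks, the concentration index and its Erreygers normalization with
    cluster-robust (primary sampling unit) standard errors, tests
    concentration-curve dominance against the line of equality with a
    multiple-comparison rule, and decomposes the Erreygers index into
    covariate contributions through a weighted linear probability model.
    Includes a clustered DHS-like synthetic data generator with known
    population truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    sandwich,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
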