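Package: gtrater
Title: Generalizability Theory for Crossed Rater-by-Item Rating Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reliability analysis of subjectively rated performance
    data under generalizability theory, built around the fully crossed
    person x item x rater random-effects design used in divergent-thinking
    creativity research. Aggregates response-level 1-5 ratings into
    average-rating, snapshot, and fluency scores; estimates the seven
    variance components of the two-facet crossed design by the expected
    mean squares (ANOVA) method; projects components to candidate designs
    to obtain relative and absolute error variance and the generalizability
    and dependability coefficients (D-study); searches for the smallest
    design reaching a target coefficient; computes convergent-validity
    descriptives; and simulates rating data from the additive crossed
    random-effects model for testing and power planning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
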