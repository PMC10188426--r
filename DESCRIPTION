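Package: carptest
Title: Conditional-Association Tests of Unidimensionality for Binary Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether a set of binary test items is consistent with a
    unidimensional monotone homogeneity model, as opposed to a
    multidimensional monotone factor structure.  Implements the CARP test
    (conditioning on added regression predictions): for a focal item pair
    the sample is split into training and test parts, the training part is
    used to estimate linear-regression weights and quantile separators for
    a weighted rest score, and a one-sided Mantel-Haenszel statistic on
    the test part checks that the pair's covariance is nonnegative within
    each quantile layer.  Also provides Rosenbaum's conditioning-on-rest-
    scores (CRS) comparator, screening of item pairs with a Bonferroni
    multiplicity rule, a multidimensional logistic latent-trait simulator,
    an exact population oracle based on Gauss-Hermite quadrature and full
    pattern enumeration, and seeded Monte-Carlo harnesses for Type-I-error
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
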