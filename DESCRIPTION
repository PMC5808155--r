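Package: loewe
Title: Loewe Additivity Null Reference Models for Two-Compound
    Dose-Response Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and comparison of null reference response
    surfaces for two-compound checkerboard screens under the Loewe
    Additivity principle.  Implements the implicit General Isobole
    equation solved by bracketed bisection, the explicit
    equivalent-dose surfaces obtained by substituting one compound by
    its effect-equivalent dose of the other, and their arithmetic and
    geometric mean combinations, together with fallback rules for
    compound pairs with unequal maximal effects.  Provides diagnostics
    for the Loewe Additivity Consistency Condition (the requirement
    that the two substitution orders agree, which for Hill curves holds
    exactly when the curves differ only in their half-effect dose),
    constrained four-parameter log-logistic fitting of conditional
    dose-response series with a shared zero-dose response, bias and
    mean-squared-error model evaluation with paired Wilcoxon
    signed-rank comparison, isobole (contour) extraction, and a
    synthetic checkerboard generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
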