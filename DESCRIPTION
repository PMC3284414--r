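Package: eqtariff
Title: EQ-5D-3L Tariff Algorithms, Re-Parameterization, and Collinearity
    Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the US EQ-5D-3L time trade-off tariff
    and its regression specification. Enumerates and featurizes the 243
    EQ-5D-3L health states, scores states under additive tariffs anchored
    at perfect health, converts exactly between the original D1-variable
    specification and its mathematically equivalent constant-term form,
    computes variance inflation factors over the combinatorial state
    space by auxiliary regression with an independent inverse-correlation
    cross-check, counts tariff calculation steps, enumerates tied state
    pairs, and simulates respondent-level time trade-off disutility data
    to demonstrate model equivalence, coefficient recovery, and standard
    error behavior under ordinary least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
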