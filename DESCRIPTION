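Package: partmig
Title: Seasonal Survival Analysis of Partially Migratory Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating seasonal survival of partially migratory
    bird populations from capture-mark-recapture and radio-telemetry
    presence-absence data. Implements a multi-event (hidden Markov)
    capture-recapture likelihood with logit-linear covariate effects on
    survival and detection, QAICc model selection with Akaike weights,
    seasonal encounter-history preparation with migratory-strategy
    classification and exclusion filters, a geometric-series break-even
    calculation of the breeding-success excess residents need to offset a
    migrant winter-survival advantage, and a synthetic-data generator that
    emulates the sampling design for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
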