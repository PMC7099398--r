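Package: rsvtrend
Title: Search-Volume Time-Series Decomposition and Disease-Rate Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for infodemiology studies that relate internet relative
    search volumes (RSVs) to registry disease rates. Provides a synthetic
    generator for state-level monthly RSV panels and annual age-adjusted
    incidence and mortality rates with known ground truth, classical
    multiplicative time-series decomposition (trend, seasonal, cyclical,
    irregular) with moving-average smoothing and monthly-average seasonal
    indices, per-state Spearman rank correlation of original and decomposed
    search volumes against disease rates with two-tailed t significance,
    and simple linear extrapolation of annual rates past the registry lag.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    datasets,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
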