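Package: seastack
Title: Sea Stack Plots: Grouped Vertical Histograms with Summary Overlays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sea stack plots: per-group vertical histograms drawn
    left-facing from a group baseline, overlaid with parametric (mean and
    mean +/- 1 SD) or non-parametric (median and quartile range) summary
    statistics, so that large univariate datasets can be compared across
    groups without the over-plotting of scatter plots or the smoothing
    artefacts of density plots. Includes data-driven bin-width selection
    (Freedman-Diaconis, Scott, Sturges, or fixed), shared bin edges across
    groups, seeded generators for four benchmark distributions (normal,
    zero-inflated, positively skewed with outliers, bimodal) constrained to
    a common population mean, a figure-panel survey tally with integer
    percentage arithmetic, deterministic SVG output alongside PNG and PDF,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite
Config/testthat/edition: 3
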