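Package: dendropart
Title: Zero-Growth Partitioning and Multi-Scale Analysis of Dendrometer Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to partition high-resolution stem-diameter (dendrometer)
    time series into irreversible growth (GRO) and reversible tree water
    deficit (TWD) under the zero-growth concept, and to derive annual
    (growing-season phenology, growth duration, water-deficit summaries),
    seasonal (daily aggregation, bimodal spring/autumn growth split) and
    sub-daily (hour-of-day growth probability, rate and contribution,
    night/day ratios, midnight-zeroed diel curves) metrics. Includes
    hourly climate processing (Tetens vapour pressure deficit, relative
    extractable soil water), local polynomial response surfaces over the
    vapour-pressure-deficit by soil-water hydrometeorological space with
    convex-hull trimming, a coupled synthetic climate and stem generator
    with an exact ground-truth ledger, and an end-to-end study driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    zoo,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
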