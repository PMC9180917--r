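Package: wildtrade
Title: Geopolitical Scenario Analysis for the International Trade in
    Wild-Caught Live Birds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Relates countries' geopolitical profiles (strength of trade
    barriers and degree of rule of law) to the volumes of wild-caught live
    birds they trade, and projects trade volumes under four stylised
    geopolitical futures. Provides reading and filtering of CITES-style
    trade records, supplier/demander classification, quantile-based
    geopolitical scoring, log-binned trade-volume scores, proportional-odds
    cumulative-link regression with Nagelkerke and McFadden pseudo-R2,
    fuzzy c-means clustering of countries in the governance plane,
    seeded Monte Carlo scenario projection, and a synthetic-data generator
    emulating CITES-like records with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071,
    optparse
Config/testthat/edition: 3
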