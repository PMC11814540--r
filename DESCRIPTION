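Package: heronscape
Title: Multi-Scale Colony-Site Selection Analysis for Colonial Waterbirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing colony-site selection of colonial
    waterbirds at multiple spatial scales. Generates synthetic multi-class
    land-use landscapes with a planted, recoverable scale-specific habitat
    preference; samples constrained pseudoabsence points; extracts land-use
    class areas in circular and annular buffers at a sweep of radii; fits
    per-scale random-forest ensembles and selects the scale of effect by
    out-of-bag accuracy; screens for influential outliers by random sample
    deletion; and compares landscape Shannon diversity between presences and
    pseudoabsences with normality-gated tests plus NMDS ordination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    ranger,
    vegan,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
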