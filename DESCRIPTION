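Package: colorcons
Title: Consistency Scoring and Automated Validation for Color Response Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analyzing data from synesthesia consistency tests and
    other repeated color-response paradigms. Parses tidy long-format trial
    tables, converts response colors among sRGB, CIE XYZ, CIELAB and CIELUV,
    computes per-inducer and per-participant consistency scores with published
    classification cutoffs, and classifies each participant's data as valid or
    invalid using density-based clustering (DBSCAN) of response colors together
    with a total within-cluster variance statistic. Includes screening
    arithmetic (positive predictive value), a seeded generator of synthetic
    respondent archetypes for calibration and testing, per-participant
    diagnostic plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ggplot2,
    patchwork,
    tibble,
    jsonlite,
    optparse,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
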