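Package: ensoanthro
Title: ENSO Teleconnections and Child Anthropometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end machinery for estimating the effect of the El Nino
    Southern Oscillation (ENSO) on child nutritional status: detection of
    temperature and precipitation teleconnections from gridded monthly
    climate, tropical-year exposure assignment from a monthly NINO3.4-style
    sea-surface-temperature index, survey-weighted fixed-effects panel
    estimation with two-way (year by admin1) clustered standard errors,
    Frisch-Waugh-Lovell residualization with Epanechnikov local-polynomial
    smoothing, placebo randomization, and counterfactual attribution
    arithmetic (children pushed below WHO thresholds, intervention
    equivalence, SDG pace). A seeded synthetic-world generator emulates all
    input streams with planted teleconnections and treatment effects so the
    full pipeline is testable without restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
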