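Package: hrrrmet
Title: AERMET-Format Surface Meteorology from HRRR Gridded Forecasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates AERMOD/R-LINE compatible surface meteorology (.sfc)
    files from hourly High-Resolution Rapid Refresh (HRRR) style gridded
    forecast variables under three preparation scenarios: direct derivation
    of every AERMET surface variable, physically bounded derivation, and a
    convective/stable boundary-layer split with an energy-balance sensible
    heat flux. Derived stability parameters (Monin-Obukhov length,
    convective velocity scale, Bowen ratio, albedo, wind direction) follow
    the AERMOD Model Formulation equations. Also provides the evaluation
    statistics used to compare dispersion predictions against monitor
    observations: Willmott's Index of Agreement, simple-regression
    coefficient of determination, distance-stratified comparison, and
    site-level covariate regression, plus a seeded synthetic-data generator
    so the full pipeline is testable without downloading forecast archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    geosphere,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
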