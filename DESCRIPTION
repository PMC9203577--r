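Package: neeiav
Title: Regional and Seasonal Attribution of Land Carbon Flux Interannual Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the correlation between the interannual variability of
    global annual net ecosystem exchange (NEE) and terrestrial water storage
    (TWS) or air temperature into additive per-grid-cell, per-calendar-month
    contributions, using the additivity of covariances over extensive flux
    anomalies. Includes the supporting pipeline: linear detrending of monthly
    gridded series (whole-series and per-calendar-month), area-weighted global
    aggregation, Pearson and partial correlations, dry/wet season
    classification from potential evapotranspiration versus precipitation,
    per-cell seasonal sensitivity regressions of NEE on TWS and temperature,
    atmospheric CO2 growth-rate computation, NetCDF input/output, and a
    seeded synthetic-data generator that plants known sensitivities and
    latent climate modes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ncdf4,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
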