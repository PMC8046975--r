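Package: microbuff
Title: Microclimate Buffering Analysis for Paired Below-Canopy and Open-Field Stations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how forest canopies buffer near-ground
    microclimate against open-field (macroclimate) conditions from paired
    half-hourly station records. Provides quality control and aggregation of
    sensor series, seasonal temperature-offset estimation under nested
    month/day/hour random intercepts, offset-versus-macroclimate response fits
    (harmonic mixed models and penalized splines), the buffering-capacity
    statistic (closed-form thermal-sum area between the fitted coupling line
    and the 1:1 line, split at their crossing point), hourly decoupling
    profiles, soil-temperature and snow-period summaries, and NDVI-based
    growing-season phenology metrics. A seeded synthetic-campaign generator
    with analytically known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    lubridate,
    mgcv,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
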