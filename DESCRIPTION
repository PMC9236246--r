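Package: aircrossover
Title: Time-Stratified Case-Crossover Analysis of Air Pollution and
    Emergency Department Visits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating short-term associations between ambient
    air pollution and daily counts of emergency department visits using a
    time-stratified case-crossover design. Calendar days are grouped into
    year-by-month-by-weekday clusters and cluster nuisance parameters are
    eliminated by conditioning on cluster totals, giving a conditional
    (multinomial) Poisson likelihood that is maximised by Newton iteration
    with quasi-Poisson dispersion scaling. Includes construction of daily
    city-wide exposure metrics from hourly station records, the Canadian
    Air Quality Health Index (AQHI) and its 8-hour-ozone variant,
    natural-spline weather adjustment, a full exposure-by-lag-by-stratum
    model grid with interquartile-range-scaled relative risks, and a
    synthetic-data generator emulating seasonal autocorrelated exposure
    series and overdispersed visit counts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
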