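Package: climpen
Title: Climate Penalty of Summer Temperature on Surface Air Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the sensitivity of surface PM2.5 and ozone to
    interannual summer temperature anomalies (the "climate penalty") from
    gridded and station time series. Provides a synthetic spatiotemporal
    data generator with known ground truth, completeness-filtered monthly,
    summer (JJA) and June-to-May annual aggregation, detrended-anomaly
    slope estimation per site and per grid cell, pooled regional slopes
    with year-block bootstrap confidence intervals, decadal-change and
    moving-window analysis, population- and area-weighted exposure
    distributions with high-penalty thresholds and urban stratification,
    and per-species attribution of the PM2.5 penalty.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    geosphere,
    ncdf4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
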