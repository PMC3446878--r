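Package: evisoscape
Title: Fine-Scale Precipitation Oxygen-18 Isoscapes from MODIS EVI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the oxygen-18 composition of precipitation from
    satellite vegetation-index time series. Provides upper-envelope
    Savitzky-Golay smoothing of 16-day EVI composites, growing-season
    detection and integration (iEVI), a five-parameter site-level
    iEVI-d18O model fitted by multi-start box-constrained least squares,
    cross-season transfer of the fitted kink location, elevation-gradient
    interpolation, and rasterisation of 250 m d18O isoscapes, together
    with a synthetic-data generator that makes the whole pipeline
    testable without satellite downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
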