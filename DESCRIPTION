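Package: chronopop
Title: Radiocarbon Dates-as-Data Palaeodemography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers relative prehistoric population trends from tables of
    radiocarbon dates ("dates as data"). Provides chronometric hygiene
    filtering of CARD-style date tables, grid-based calibration against
    IntCal-format curves, Sheather-Jones kernel density and dated-site-count
    population proxies on a 100-year calendar grid, Surovell-style taphonomic
    bias correction, subsampling bootstrap confidence envelopes, quasi-Poisson
    GLM/GAM trend fitting with GCV-selected smoothness, and detection of
    significant periods of population growth and decline from the first
    derivative of the fitted trend. Includes a synthetic radiocarbon record
    generator with known population structure for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
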