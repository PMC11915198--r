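Package: firestops
Title: Attribution of Wildfire Cessation Drivers Along Fire Perimeters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts fire stops (unburned 300 m pixels along wildfire
    perimeters) from day-of-burn rasters and attributes each stop to
    top-down fire-weather drivers (fuel moisture via vapor pressure
    deficit and soil moisture, wind fire spread index) and bottom-up
    landscape drivers (surface water, roads, burn history, fuel load,
    land cover, downslope) using two-stage time-series tests with
    multiple-breakpoint detection, perimeter-perpendicular ellipse
    sampling with t and chi-squared tests, and a hierarchical decision
    tree with normalized driver contributions. Includes a synthetic
    scenario generator with planted, labeled cessation causes so the
    whole pipeline can be validated against a known ground truth, plus
    equal-area grid aggregation, seasonal summaries and OLS trend
    analysis of driver contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
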