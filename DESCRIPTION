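Package: budbreakr
Title: Chilling-Forcing Bud-Break Models for Boreal Scots Pine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Process-based modelling of spring bud break in Scots pine at
    high latitudes. Implements a sigmoidal temperature response for forcing
    accumulation and a piecewise-linear chilling response, combined into a
    sequential chilling model and a fixed-date (day-length proxy) model.
    Derives observed bud-break dates from weekly leader-shoot growth
    measurements by linear interpolation, calibrates model parameters to
    observations with a bounded genetic algorithm minimising RMSE,
    reconstructs century-long bud-break series from daily station
    temperature records with offset adjustment and missing-year omission,
    and tests for linear trends under autoregressive errors by maximum
    likelihood and ordinary least squares. Includes a synthetic generator
    for subarctic daily temperature series and tree-growth measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nlme,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
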