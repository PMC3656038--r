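Package: wheatsoc
Title: Four-Pool Soil Organic Carbon Dynamics and Regional Carbon Accounting
    for Wheat Cropping Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily-time-step, four-pool first-order model of soil organic
    carbon (SOC) turnover in cropped topsoil (labile, resistant, light and
    heavy carbon pools with inter-pool transfer fractions), together with the
    machinery needed to apply it at regional scale: conversion of annual crop
    yields into soil carbon inputs via residue ratios, root fractions and
    stubble-retention rates; spin-up initialisation and steady-state analysis;
    depth harmonisation of SOC observations and model-evaluation statistics
    (RMSE, relative mean deviation, model efficiency, regression checks);
    exhaustive grid-search calibration of the kinetic parameters; and Monte
    Carlo propagation of soil-property and carbon-input uncertainty to
    decadal, area-weighted regional carbon-stock accounts with empirical
    confidence intervals. Includes generators for synthetic daily climate,
    yield series, site trials and multi-region fixtures so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
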