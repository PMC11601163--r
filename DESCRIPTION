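Package: cycovar
Title: Removal of Unwanted Covariance from Mass Cytometry Data
Version: 0.1.0
Authors@R: person("Pkg", "Maintainer", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Mass cytometry (CyTOF) marker intensities are confounded by
    cell size and staining efficiency, which have no direct instrument
    readout. This package regresses each marker, per cell, on surrogate
    channels of those confounders (mean DNA-intercalator signal, mean
    barcode signal, abundant loading-control proteins) or on principal
    components thereof, using simple, per-sample-offset, or per-sample
    interaction linear models, and replaces the marker by intercept plus
    residual. Includes the evaluation metrics (marker correlations,
    standard-deviation change, asinh fold changes, energy distance,
    threshold classification), a synthetic confounded-data generator with
    linear and quadratic cell-size artefacts for validation, minimal
    FCS/CSV input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
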