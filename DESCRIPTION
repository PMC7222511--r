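Package: initrate
Title: Initial Rates and Kinetic Parameters from Continuous Enzyme Kinetic Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes initial reaction rates from continuous enzyme kinetic
    traces (plate-reader time courses) by four extraction modes: automatic
    maximum-slope selection on a smoothing-spline derivative, windowed linear
    regression, a logarithmic approximation of the integrated Michaelis-Menten
    equation, and a global fit of the Schnell-Mendoza closed-form
    Michaelis-Menten progress curve via the Lambert W function. Propagates
    rate standard errors into weighted Michaelis-Menten, four-parameter
    logistic EC50/IC50, and high-throughput-screening hit-flagging models.
    Includes a synthetic-trace generator with known ground truth and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    deSolve,
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
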