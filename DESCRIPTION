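Package: dtofsens
Title: Depth-Selective Sensitivity Analysis for Time-Domain Diffuse Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the depth sensitivity of time-domain
    near-infrared diffuse reflectance measurements through statistical
    moments of photon time-of-flight distributions (DTOFs). Implements
    single-distance, single-subtraction and dual-subtraction moment
    analysis, diffusion-theory forward modelling of semi-infinite media
    with Born-level absorption Jacobians, moment-based estimation of
    optical properties, an in-silico liquid-phantom sweep simulator with
    instrument-response broadening and Poisson counting noise, photon-noise
    error propagation for the moments, and depth-selectivity /
    contrast-to-noise performance metrics.
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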