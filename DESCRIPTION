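Package: marshpace
Title: Probabilistic Assessment of Coastal Wetland Vertical Resilience to
    Water-Level Rise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess whether coastal wetland monitoring sites can
    vertically keep pace with rapid relative water-level rise. Implements
    quality control and deseasonalization of gauge and surface-elevation
    series, ordinary-least-squares trend estimation with AR(1) red-noise
    surrogate significance testing, Monte Carlo trend ensembles, a
    probabilistic differential vertical-land-motion correction, a
    seven-category give-up/keep-up/catch-up/speed-up wetland response
    classification, surface-elevation-deficit statistics, and
    threshold-crossing analysis against decadal sea-level-rise projection
    curves. Includes a synthetic monitoring-network generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
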