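Package: rootsoc
Title: Fine-Root and Soil Organic Carbon Stock Profiles Across Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline linking fine-root carbon (FRC) stocks to soil
    organic carbon (SOC) stocks across megapit-style site profiles. Aligns
    fixed-depth root increments onto taxonomic soil horizons, computes layer
    and whole-profile carbon stocks, estimates exponential depth-distribution
    (beta) coefficients for roots and SOC, scores standardized 1:1-line
    residuals as an inferred SOC accrual/priming statistic, and selects
    linear and mixed-effects models by AIC/AICc. Includes a synthetic
    continental-gradient site generator with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
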