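Package: rctppmm
Title: Proxy Pattern-Mixture Sensitivity Analysis for Generalizing
    Randomized Trial Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sensitivity analysis for nonignorable selection into a
    randomized controlled trial when generalizing treatment effects to a
    target population described only by summary-level covariate data.
    Implements the proxy pattern-mixture model for RCTs (RCT-PPMM):
    per-arm outcome proxies built from baseline covariates, closed-form
    adjusted means indexed by bounded sensitivity parameters, tipping-point
    analysis, fully Bayesian inference with Jeffreys priors and uniform
    priors on the sensitivity parameters, M-estimation (sandwich) standard
    errors at fixed sensitivity values, and a simulation framework with
    unequal-probability fixed-size (Brewer) sampling for studying interval
    coverage under nonignorable selection mechanisms.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
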