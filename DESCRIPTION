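Package: seasonpower
Title: Power Analysis for Seasonal and Clustered Surveillance Designs
Version: 0.1.0
Authors@R:
    person("Field Surveillance Methods", "Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Sample-size and design optimisation for longitudinal ecological
    surveillance (mosquito surveys in particular), where repeated measurements
    at the same location are temporally correlated through a dampened
    autoregressive seasonal process and locations are spatially clustered.
    Implements the classic t-test and Taylor's power law sample sizes, the
    repeated-measures sample size with a dampened AR correlation, cluster
    sample sizes with the variance inflation factor, an exact noncentral-F
    small-sample adjustment, and a grid-search optimiser that balances the
    number of repeated measurements against the number of survey locations.
    Includes a seeded Gaussian-process simulator for seasonal abundance
    curves and a command-line interface with CSV and plot outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
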