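Package: threshtrial
Title: Threshold-Crossing Single-Arm Trial Designs with Historical Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design and evaluation of threshold-crossing clinical trials:
    single-arm studies judged against an efficacy threshold derived from
    historical control data. Provides closed-form sample-size calculations
    for parallel-group and single-arm designs with a normally distributed
    endpoint, threshold rules based on the observed historical mean or the
    upper confidence bound (optionally inflated by a fraction of the
    standardized effect), fixed- and random-effects (DerSimonian-Laird)
    pooling of multiple historical cohorts, an exact closed-form oracle for
    the marginal rejection probability, a seeded Monte Carlo engine for
    operating characteristics (power, type-I error, control-mean drift
    sensitivity) over scenario grids, and simulation of the multistage
    efficacy/promising/futility decision pathway with roll-over to a
    randomized controlled trial or a second single-arm stage.
License: MIT
Encoding: UTF-8
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
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
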