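Package: firearmsdm
Title: Spatiotemporal Estimation of State-Level Firearm Ownership
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates monthly state-level firearm ownership from administrative
    proxies (background checks per capita and the fraction of suicides committed
    with a firearm) using a time-varying spatial Durbin panel model calibrated by
    maximum likelihood on annual October survey anchors. Includes row-stochastic
    population/distance weight matrices, a Monte-Carlo log-determinant, iterative
    monthly prediction with survey anchoring, a seasonal-adjustment and
    symbolization pipeline, conditional transfer entropy with a stratified local
    permutation test, and a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    geosphere,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
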