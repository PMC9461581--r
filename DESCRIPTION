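Package: socforage
Title: Coupled Evidence-Accumulation Models of Social Patch Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and inference tools for groups of foragers deciding
    when to leave a depleting resource patch. Each forager's belief evolves as
    a drift-diffusion process whose drift tracks patch depletion; beliefs are
    coupled between group members either diffusively (continuous sharing) or
    pulsatilely (a jump delivered when a neighbour decides). The package
    provides an Euler-Maruyama Monte Carlo engine for departure-time data,
    closed-form and Fokker-Planck first-passage machinery for the uncoupled
    and perfectly coupled limits, reward-rate evaluation and optimisation of
    group strategies, and Bayesian MAP estimation with Bayes-factor model
    comparison on ordered departure-time pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
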