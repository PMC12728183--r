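Package: lenscue
Title: Simulating Cue-Predictivity Experiments on Context Effects and
    Nudges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A stochastic simulator of three-alternative incentivised
    choice experiments in which an experimental manipulation (a dominated
    decoy, a pre-selected default, or an indicator shape) acts as a
    probabilistic cue for the highest-payoff option, together with
    synthetic choice agents (random, attribute-maximising, fixed cue
    weight, probability matching) and the preregistered analysis
    pipeline: test-round subsetting, linear probability regressions of
    cue-following on historical cue predictivity with cluster-robust
    standard errors, marginal effects, binned choice rates and analytic
    chance benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
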