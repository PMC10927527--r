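Package: misinfogame
Title: The Misinformation Game: Strategic News Transmission and Engagement Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the strategic interplay between news producers
    (transmitters) and news consumers (receivers) in an asymmetric, infinitely
    repeated "misinformation game". Transmitters choose whether each story is
    true or false with engagement-dependent feedback rules; receivers decide
    whether to engage using attention-limited behavioural strategies. The
    package computes the exact stationary distribution of the joint Markov
    chain, the linear outcome constraint a fixed transmitter strategy enforces
    on any receiver, Fermi-rule myopic strategy optimization and
    co-optimization, random-search ensembles over viable transmitter strategies
    with classification of enforcement structure, simulated story-sequence
    engagement/accuracy regressions, and a statistical toolkit (per-site
    accuracy-engagement regression, Fisher's combined test, DerSimonian-Laird
    random-effects meta-analysis, and rating-level regression with two-way
    cluster-robust standard errors) validated on synthetic data generators
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    metafor,
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
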