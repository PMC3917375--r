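Package: runtumble
Title: Veto-Model Analysis and Stochastic Simulation of Bacterial
    Run-Tumble Swimming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links single-flagellum rotational statistics to whole-cell
    run/tumble swimming in multi-flagellated bacteria. Implements the
    veto-model algebra relating tumble bias, clockwise bias and flagellar
    number, the eta deviation statistic and the effective-flagellar-number
    generalization with its power-law summary; a stochastic simulator of
    CheY-P-driven multi-flagellar motor switching (Ornstein-Uhlenbeck
    signaling noise, Hill response, telegraph motors, flagellar waveform
    overlays and run/tumble rules); trace-level estimators (biases, tumble
    events, pairwise cross-correlations, switching and waveform rates);
    calibration of the fluctuation parameters by reduced chi-squared grid
    scan; and a synthetic-data generator emulating windowed single-cell
    observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
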