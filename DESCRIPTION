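Package: fapr
Title: Future Average Production of Dairy Cows from Herd Recording Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the expected future average production value of milk
    (kg/day, corrected for the somatic-cell price penalty) for every dairy
    cow on every test day, from routine herd recording data alone.  Fits
    herd-level lactation and total somatic cell count curves with per-cow
    multiplicative levels, inter-lactation level correlations, sigmoid
    survival curves in days open, and exponentially smoothed cow levels;
    combines them into a survival-weighted future average production (FAP)
    suitable for ranking cows for culling.  Includes a seeded synthetic-herd
    generator with known ground truth and a validation harness comparing
    FAP against naive predictors of realized future production.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    minpack.lm,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
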