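Package: dielstarch
Title: Diel Starch Turnover Kinetics and Circadian Transcript Rhythm Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying diel (light/dark cycle) starch turnover and
    circadian transcript rhythms in plant time-series experiments. Estimates
    absolute and dusk-normalized rates of starch accumulation and mobilization
    by linear models on replicate data, projects the time of starch exhaustion
    by single (StEx) and nested dusk-anchored (apparent StEx, geometric-mean)
    extrapolation, scores deviation of night-time mobilization from linearity
    with bootstrap confidence intervals, estimates peak time and amplitude of
    oscillating transcripts by AICc-selected polynomial and spline fits on
    bootstrapped series, and scores dawn versus dusk alignment of transcript
    profiles across photoperiods (DIST/NORM). Includes a synthetic diel
    time-series generator emulating photoperiod, T-cycle and light-perturbation
    designs so every analysis stage is testable without external data.
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
    utils,
    car,
    multcomp,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
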