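Package: catrace
Title: Cell-Type-Resolved Calcium Imaging Analysis for Cued Reward Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium imaging recorded during
    head-fixed auditory cued reward conditioning: iterative percentile baseline
    (F0) estimation and trial-baseline z-scoring of ROI fluorescence traces,
    circular-shift permutation detection of significant activity events,
    trial-by-trial stimulus responsiveness and reliability indices with
    Monte-Carlo resampled null distributions, Spearman tuning coefficients with
    bootstrap/trial-scramble nulls, lick-bout behavioral metrics and
    licking-confound controls, and a synthetic-session generator with ground
    truth for calibration and parameter-recovery studies. Results are returned
    as tidy tibbles with broom-style tidiers and ggplot2 diagnostics.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
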