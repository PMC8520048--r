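Package: evospike
Title: Comparing Stimulus-Evoked and Spontaneous Multi-Unit Spiking Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for comparing stimulus-evoked multi-unit
    firing with spontaneous (prestimulus and resting-state) activity.
    Provides a calibrated inhomogeneous-Poisson generator for synthetic
    task and resting spike-train sessions, epoch extraction around stimulus
    onsets, instantaneous firing-rate estimation by Gaussian-kernel
    smoothing, normalized rate-distribution histograms, per-trial power
    spectra of short spike-train segments, two-tailed nonparametric
    cluster-based permutation tests for evoked modulation and category
    selectivity, and a bootstrap window-ranking statistic that measures the
    percentage of spontaneous windows among the top-firing spike-count
    windows as a function of window length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    optparse,
    tidyr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
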