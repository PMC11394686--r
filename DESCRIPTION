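Package: lfpband
Title: Movement-State Band-Power Analysis of Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transient, movement-related changes in
    local field potential (LFP) band power in hemiparkinsonian (6-OHDA) versus
    sham rodents. Conditions multi-channel recordings (zero-phase band-pass
    filtering, artifact-free segment selection, fixed-length epoching),
    estimates Welch power spectra, integrates power over the delta, theta,
    alpha, beta and gamma bands, forms the per-subject walking-minus-resting
    difference statistic, and analyses it with a split-plot (mixed
    repeated-measures) ANOVA with Mauchly sphericity testing,
    Greenhouse-Geisser correction and Fisher LSD post hoc comparisons.
    Includes an assumption-driven two-sample test cascade (Shapiro-Wilk,
    Levene, transform-and-retest, t or Mann-Whitney U) for behavioral and
    histological endpoints, the cylinder asymmetry ratio and gait support
    metrics, TH+ neuron density summaries, and a synthetic data generator
    (1/f background plus state- and group-dependent band-limited
    oscillations) with known ground truth for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite,
    yaml,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
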