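Package: vigicor
Title: EEG-Vigilance Staging and Personality Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the link between resting-state brain arousal
    and personality traits. Implements VIGALL-style classification of 1-second
    eyes-closed EEG segments into seven vigilance stages from regional
    alpha and delta+theta current densities, reduces stage sequences to the
    standard arousal summary metrics (mean vigilance, stability score, slope
    index), and provides the accompanying inference stack: Spearman and
    covariate-adjusted Spearman association matrices with Benjamini-Hochberg
    FDR control, correlation Bayes factors under a stretched symmetric beta
    prior computed from the exact sampling distribution of the correlation
    coefficient, structured permutation nulls with quantile-quantile
    envelopes, and correlation power analysis. A calibrated synthetic cohort
    generator emulates the statistical structure of a large population
    resting-EEG study so the full pipeline is testable without access to
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
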