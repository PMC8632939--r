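Package: emoshift
Title: Paired Emotion and Language Shift Analysis for Two-Wave Survey Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing repeated-measures emotion surveys with
    accompanying free text, collected in two waves from the same
    participants. Provides cohort cleaning and pairing with reproducible
    exclusion bookkeeping, paired effect sizes with Jeffreys-Zellner-Siow
    (JZS) Bayes factors computed by log-space quadrature, k-means subgroup
    discovery on emotion-change vectors with elbow and silhouette model
    selection, dictionary-based psycholinguistic category scoring, a
    within-subject n-gram shift statistic based on the Wilcoxon signed-rank
    test with randomised tie ranks, and a synthetic two-wave cohort
    generator with planted change-clusters and vocabulary shifts for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
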