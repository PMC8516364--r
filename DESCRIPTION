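Package: mythscore
Title: Intratumour Heterogeneity Scoring from DNA Methylation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores intratumour heterogeneity (ITH) of bulk tumour samples
    from gene-level DNA methylation beta values. Each sample's score is the
    spread (a standard-deviation-style estimator) of its per-gene deviations
    from the cohort mean methylation profile. Includes single-sample gene set
    enrichment (ssGSEA) for signature scoring, nonparametric association
    statistics (Spearman correlation, one-tailed Mann-Whitney U, score
    tertiles, Kaplan-Meier curves and the log-rank test), a clonal-mixture
    simulator that generates methylation cohorts with known per-sample
    heterogeneity and purity, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
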