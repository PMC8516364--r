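# mythscore

Intratumour heterogeneity (ITH) — the diversity of cell subpopulations
within one tumour — drives progression and therapy resistance, but most ITH
estimators work at the DNA mutation or mRNA level. `mythscore` quantifies
ITH from **DNA methylation** profiles: given a gene-level beta-value matrix
for a tumour cohort, each sample is scored by how widely its per-gene
methylation deviates from the cohort mean profile.

## The score

For a tumour sample *TS* in a cohort of *t* samples profiled on *m* genes,
let β(G<sub>i</sub>, TS) be the methylation level of gene G<sub>i</sub> and

&nbsp;&nbsp;&nbsp;&nbsp;Δ<sub>i</sub> = β(G<sub>i</sub>, TS) − (1/t) Σ<sub>j</sub> β(G<sub>i</sub>, CS<sub>j</sub>)

the deviation from the cohort mean. The score of *TS* is

&nbsp;&nbsp;&nbsp;&nbsp;MYTH(TS) = sqrt( (1/(m−1)) Σ<sub>i</sub> Δ<sub>i</sub>² − ( (1/m) Σ<sub>i</sub> Δ<sub>i</sub> )² )

a standard-deviation-style spread of the deviation profile. A homogeneous
tumour sitting near the cohort consensus scores ≈ 0; a tumour whose clones
pull many genes away from the consensus scores high. This exact ("printed")
form is the default; note it mixes a 1/(m−1) sum of squares with a squared
1/m mean, so the textbook sample standard deviation is available as
`estimator = "unbiased"` (see the methods vignette).

The package also provides the downstream toolkit such a score is used with:
single-sample gene set enrichment (ssGSEA) for signature scoring, Spearman
correlation, one-tailed Mann–Whitney U tests, score tertiles with
Kaplan–Meier/log-rank survival comparison, and a clonal-mixture simulator
that generates methylation cohorts with known per-sample heterogeneity,
purity and survival linkage.

## Worked example

```r
library(mythscore)

# a simulated 2000-gene cohort: 200 tumours whose clonal divergence varies,
# plus 50 matched normals (no clonal structure)
cohort <- simulate_cohort(n_genes = 2000, n_samples = 200, n_normals = 50,
                          seed = 1)
cohort <- attach_survival(cohort, baseline_hazard = 0.1,
                          log_hazard_per_divergence = 1.5,
                          censor_rate = 0.2, seed = 2)

fit <- myth(cohort$beta)            # printed estimator, min_genes = 100
normals <- predict(fit, cohort$normals)   # scored on the tumour reference

spearman_cor(cohort$truth$divergence, coef(fit))
#> Spearman rho = 0.9010, p = 9.96e-74 (n = 200)

median(coef(fit)); median(coef(normals))
#> [1] 0.0503
#> [1] 0.0209

mann_whitney(coef(fit), coef(normals), alternative = "greater")$p_value
#> [1] 5.44e-28

surv <- survival_tertile_test(coef(fit), cohort$survival$time,
                              cohort$survival$event)
surv$logrank
#> Log-rank chi-square = 28.9160 (1 df), p = 7.56e-08
```

The score recovers the simulated ground-truth clonal divergence
(ρ = 0.90), normal controls score about half the tumour median on the
tumour cohort's own reference, and with heterogeneity linked to hazard the
upper score tertile shows clearly worse survival than the bottom tertile —
the three qualitative behaviours an ITH score must reproduce.

## Command line

A thin wrapper over the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "myth.R", package = "mythscore"))')" \
    score --input matrix.tsv --output scores.tsv --min-genes 100
```

Subcommands: `score`, `ssgsea`, `associate`, `simulate`. Every run writes a
JSON manifest (version, full parameter set, input digests, timestamp) next
to its output so results can be reproduced exactly.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package — simulates a cohort with normals and linked survival,
scores it, and recomputes the recovery correlation, the normal-vs-tumour
comparison and the tertile survival test, logging each result:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
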