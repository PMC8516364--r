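---
title: "Scoring intratumour heterogeneity from methylation profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring intratumour heterogeneity from methylation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mythscore)
```

## The model

Bulk tumour methylation is a cell-population average. When a tumour is a
mixture of epigenetically divergent clones, its per-gene beta values drift
away from the cohort consensus in many directions at once; a homogeneous
tumour sitting near the consensus does not. The score summarises exactly
that: for sample $TS$ in a cohort of $t$ samples over $m$ genes, with
deviations
$$\Delta_i = \beta(G_i, TS) - \tfrac{1}{t}\sum_{j=1}^{t}\beta(G_i, CS_j),$$
the score is
$$\mathrm{score}(TS) = \sqrt{\tfrac{1}{m-1}\sum_i \Delta_i^2 -
  \Big(\tfrac{1}{m}\sum_i \Delta_i\Big)^2}.$$

Assumptions worth making explicit:

* **The cohort mean is a meaningful reference.** The score measures
  deviation spread relative to the profiled cohort, so it should be
  computed per cohort (e.g. per cancer type); pan-cohort analyses should
  concatenate per-cohort results rather than pooling matrices, since
  pooling would let between-cohort differences masquerade as
  heterogeneity.
* **The scored sample is part of the reference.** The defining mean runs
  over *all* $t$ tumour samples; the notation separating $TS$ from $CS_j$
  could also be read as excluding it. We include it by default (the index
  set does not exclude $TS$, and at cohort sizes of interest the
  difference is $O(1/t)$); `reference = "loo"` gives the leave-one-out
  alternative.
* **Scale-agnostic.** The formula uses only differences, so M-value
  matrices work too; out-of-[0,1] inputs are flagged, never rejected.

### The two estimators

The defining expression mixes a $1/(m-1)$ sum of squares with the square
of a $1/m$ mean, so it is *not* exactly the textbook sample standard
deviation of $\Delta$ — for constant deviations $d$ it returns
$|d|\sqrt{1/(m-1)}$ rather than 0. Whether that mixing is intentional or a
typesetting artifact of the sample-SD formula cannot be resolved from the
definition alone, so the package implements the expression literally as
`estimator = "printed"` (the default: fidelity first) and offers
`estimator = "unbiased"`, $\mathrm{sd}(\Delta)$, as the statistically
orthodox option. In practice $\bar\Delta \approx 0$ for most samples and
the two nearly coincide.

Numerical choices: deviations are summarised in two passes (explicit mean,
then squared terms) because the printed form subtracts two nearly equal
quantities; R's long-double accumulation in `sum()` covers the rest. The
radicand is mathematically non-negative, so a negative value can only
arise from floating point and is clamped to zero rather than raised as an
error. Per-sample scores require `min_genes` (default 100, configurable)
non-missing deviations — a standard deviation over a handful of genes is
noise — and return `NA` with a warning below that.

### Scoring external samples

Normal controls (or any external samples) are scored with
`predict(fit, newdata)` / `score_against_reference()`: deviations are
taken from the *tumour* cohort's stored means, never re-centred on the
external samples. Re-centring would erase exactly the signal being
measured — how far normals sit from the tumour consensus spread.

## Probe aggregation

Gene-level input is the native unit. For probe-level (450K-style)
matrices, `aggregate_probes_to_genes()` takes the unweighted mean of a
gene's non-missing probes. No probe-selection rule (promoter-only,
island-only) is applied: none is defensible as a universal default, and
the choice is orthogonal to the score itself. Users with opinions should
aggregate upstream and supply gene-level data.

## ssGSEA

Signature levels (stemness, proliferation, immune, pathway activity) are
computed by single-sample gene set enrichment: genes are ranked by value
(descending; ties take average ranks for weighting and stable input order
for list position), and the enrichment score is the *integrated* running
difference between the weighted in-set CDF (weights $\mathrm{rank}^\alpha$,
$\alpha = 0.25$ by default — the widely used convention) and the uniform
out-of-set CDF. The integrated sum, rather than the maximum deviation, is
what distinguishes ssGSEA from classic GSEA. Optional normalisation
divides all raw scores by the pooled max−min range. The module is agnostic
to the molecular level: beta values and expression are ranked identically.
The specific marker-gene lists used in published analyses are not bundled;
any GMT file can be supplied.

## Association toolkit

All reported p-values are raw (`bh_adjust()` exists but is never applied
implicitly). Spearman correlation uses tie-aware average ranks with the
$t$-approximation p-value at all $n \ge 3$, matching common
statistical-package behaviour at cohort sizes. The one-tailed Mann–Whitney
U test is exact by enumeration when both groups have ≤ 10 observations and
no ties, and otherwise uses the normal approximation with tie and
continuity corrections; the direction must always be stated explicitly,
because directional tests with silent defaults invite sign errors.
Survival comparison follows the upper-vs-bottom-third protocol:
`tertile_groups()` (floor(n/3) in each outer tertile, stable ties), drop
the middle, log-rank on the rest. Kaplan–Meier estimation and the log-rank
statistic are delegated to the `survival` package behind this interface;
the test suite checks them against hand-computed product-limit and
hypergeometric values.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates the stated world for validation: a consensus
beta profile per gene from a symmetric Beta distribution; per sample, a
clone count, Dirichlet mixing weights, and clone profiles perturbed from
the consensus on the logit scale with Gaussian deviations of SD =
divergence; bulk = purity × clone mixture + (1 − purity) × consensus, plus
logit-scale measurement noise, squashed back to [0, 1]. Normals are
consensus + noise only. Ground truth per sample is the *realized*
divergence (mixture-weighted mean |logit deviation|), because with a
finite gene panel the nominal SD parameter is a biased yardstick.

Defaults, chosen once: 2000 genes × 200 samples with per-sample divergence
uniform on (0.1, 1.5) and noise SD 0.1 (the stated recovery conditions);
2–5 clones per tumour and purity uniform on (0.5, 0.95), typical
bulk-tumour ranges; consensus concentration 0.5, giving the bimodal
U-shaped genome-wide beta distribution characteristic of methylation
arrays. Randomness comes from R's Mersenne-Twister with a documented draw
order (consensus first, then per sample: divergence, clone count, weights,
purity, clone deviations, noise; normals last), so fixtures are stable
across platforms.

What the simulator deliberately lacks: probe-level spatial correlation,
CpG-island architecture, copy-number-driven methylation artefacts, and
batch structure. A green recovery test therefore establishes that the
score tracks clonal divergence *under this generative model*, not that it
is robust to every artefact of real array data.

Purity mixes clones with the consensus ("stromal") profile, so higher
purity mechanically increases deviation spread — the simulator reproduces
the positive purity–score association seen empirically through a single
mechanism. `attach_survival()` adds exponential event times with hazard
$\lambda_0 e^{\gamma \cdot \mathrm{divergence}}$ and exponential censoring
whose rate is tuned per sample so the expected censoring fraction matches
the request. `embed_signature()` shifts member genes by effect × realized
divergence on the logit scale, creating known-direction targets for
score-vs-ssGSEA correlation tests.

## Testing choices

Acceptance-level checks run at stated scales: oracle equivalence on 100
random matrices against a literal loop-based re-derivation (1e-12 relative
tolerance); exact algebraic invariances (per-gene offsets, positive
scaling, permutations); divergence recovery at simulator defaults
(Spearman ≥ 0.8, seed 42); normals-vs-tumours direction (seed 17); and the
survival pipeline (seed 7) including a null calibration — 200 replicates
with constant divergence and unlinked survival, whose log-rank p-values
must pass a Kolmogorov–Smirnov uniformity check at level 0.01. The null
replicates use 150 genes × 60 samples each: large enough for the log-rank
approximation to behave, small enough to keep the suite inside a desk-scale
time budget.

## Known limitations

* The score conflates clonal heterogeneity with any other source of
  deviation from the cohort mean (batch effects, outlier biology); it
  should be interpreted within a homogeneously processed cohort.
* No gene filtering (variance, missingness) is applied before scoring
  beyond the `min_genes` guard; whether upstream filtering improves the
  score is untested here.
* The tertile survival protocol discards the middle third by design;
  direction of effect is left entirely to the caller's interpretation.
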