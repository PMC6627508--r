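---
title: "Multi-study meta-analysis of tumor expression: models, benchmarks and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-study meta-analysis of tumor expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungmeta)
```

## The problem

Transcriptomic conclusions about tumors rarely replicate cleanly from one
cohort to the next: studies differ in platform, sample procurement,
clinical curation and patient mix. A tempting shortcut is to pool all
samples from all studies into one big design matrix, but when studies carry
their own location/scale structure ("batch" effects) this pooled analysis
can manufacture arbitrarily significant artifacts. The defensible
alternative is a two-stage design: estimate an effect *within* each study,
on a scale that is comparable across platforms, then combine the per-study
estimates with a random-effects meta-analysis that prices in between-study
heterogeneity. `lungmeta` implements that design for three per-study
estimators, wraps the study/gene inclusion rules commonly used in
multi-cohort lung-cancer work, and ships a synthetic multi-study cohort
generator with known ground truth so that every claim the package makes is
tested against a data-generating process where the right answer is known.

## Per-study effect models

**Tumor-vs-normal difference.** For each gene, Hedges' G: the mean
difference between tumor and normal samples divided by the pooled SD, times
the small-sample correction $J = 1 - 3/(4(n_1+n_2-2)-1)$, with variance
$(n_1+n_2)/(n_1 n_2) + g^2/(2(n_1+n_2))$. Being unitless, it is comparable
across platforms with different dynamic ranges. Genes with zero pooled
variance in a study are masked for that study rather than failing the run.

**Survival association.** A univariate Cox proportional-hazards fit of
overall survival on expression standardized to mean 0 / SD 1 over the
study's *tumor* samples, so the coefficient is a log hazard ratio per 1 SD
of expression. Tied event times use the Efron correction (the accepted
default, and it matters on coarse follow-up grids). Fits that hit the
iteration cap or drift toward infinite coefficients (monotone-likelihood
separation) are flagged and excluded, as are studies with fewer than two
events. Standardization scope is a flag (`tumor_only` default, `all`
available): survival is a property of the tumor cohort, and tumor-only
scope keeps the per-1-SD interpretation independent of each study's
tumor/normal mix.

**Gene-gene correlation.** The Pearson correlation over tumor samples,
carried on the Fisher-z scale ($\operatorname{atanh} r$, variance
$1/(n-3)$) where normal-theory pooling is accurate; correlations are
clamped to $|r| \le 1 - 10^{-12}$ before the transform so degenerate
perfect correlations remain finite.

## Random-effects pooling

Per gene, DerSimonian–Laird: fixed-effect weights $w_i = 1/v_i$ give
Cochran's $Q$; $\hat\tau^2 = \max\{0, (Q - (k-1))/(\sum w - \sum w^2 /
\sum w)\}$; random-effects weights $1/(v_i + \hat\tau^2)$ produce the
summary, its SE, Wald z and two-sided normal p, a 95% CI and $I^2$.
DL is the classical closed-form default; REML is available behind
`method = "REML"` and the Knapp–Hartung small-$k$ adjustment behind
`knapp_hartung = TRUE`, both for sensitivity analyses (both cross-checked
against `metafor` in the test suite). Inclusion rules follow standard
multi-cohort practice: a study contributes to the tumor-vs-normal analysis
only with at least 10 samples in each group, to survival/correlation
analyses only with at least 10 informative samples, and a gene is reported
only when at least 3 qualifying studies contribute. Correlation
meta-analysis pools on the z scale and back-transforms for reporting;
hazard ratios are exponentiated in forest tables. Bonferroni and
Benjamini–Hochberg columns are appended to every results table.

### A calibration caveat that the tests quantify

Under a *homogeneous* null ($\tau^2 = 0$) the DL procedure is mildly
conservative at small $k$: whenever sampling makes $Q > k-1$, $\hat\tau^2 >
0$ inflates the summary SE. Direct simulation of the DL process (exact
normal inputs, 200k genes) puts the resulting sup-deviation of the p-value
CDF from uniform at about 0.036 for $k = 8$ and 0.034 for $k = 10$ — all of
it on the conservative side. The package therefore reports both the
two-sided KS statistic and the one-sided anti-conservative deviation in its
inflation experiment; the latter is the quantity that detects false-positive
inflation, and for the meta path it sits near 0.001 in the benchmark runs
while CI coverage stays within [0.92, 0.98].

## The pooled-vs-meta permutation experiment

`inflation_experiment()` permutes tumor/normal labels within each study of
a cohort, then runs (a) the pooled-sample Welch t-test over all
concatenated samples and (b) the per-study Hedges' G + meta-analysis path
on identical permuted data. Welch was chosen for the pooled test as the
conservative default for unequal variances — any inflation it shows is not
an artifact of a naive equal-variance test. Labels are permuted
within-study by default, preserving each study's composition (the driver of
the effect); a global permutation is available behind a flag. One
permutation replicate per experiment is the default, as the demonstration
needs only one QQ curve per path.

The mechanism deserves spelling out, because it constrains the generator
design. Let study $s$ carry an additive per-gene offset $b_{sg}$ shared by
all its samples. In the pooled contrast the offsets enter as $\sum_s b_{sg}
(n_{T,s}/N_T - n_{N,s}/N_N)$ — which is *identically zero* when every study
has the same tumor fraction, and grows with the spread of tumor fractions
across studies. Unequal tumor/normal availability across cohorts is both
what real multi-study collections look like (adjacent-normal tissue is
scarce and unevenly collected) and the lever that makes pooling
anti-conservative: the offset term does not shrink with total sample size
while the t denominator does. The generator therefore draws each study's
tumor fraction from a range (default U(0.25, 0.85)). At batch shift SD 1.0
with 10 studies and 5000 genes this yields a pooled-path
Bonferroni-significant fraction around one third of all genes under a label
permutation — while the meta path keeps essentially none — and the fraction
is monotone in the batch shift SD.

`pca_separation()` supplies the companion per-study QC: samples are
projected on the first two principal components and the tumor/normal
partition is scored by mean silhouette width, replacing a visual judgment
with a number (silhouette was chosen because it is bounded, symmetric, and
interpretable at a glance; scores above ~0.25 correspond to the clearly
separated studies).

## The synthetic cohort generator

`synthetic_config()` + `generate_cohort()` define the study conditions used
throughout the tests and the acceptance script:

* **Expression.** Gene $g$ in study $s$: normals $\sim N(\mu_g + b_{sg},
  (\sigma_g c_s)^2)$, tumors shifted by $\delta_{sg} \sigma_g c_s$ with
  $\delta_{sg} \sim N(\mathrm{SMD}_g, \tau^2)$. Baselines $\mu_g \sim
  N(7, 2^2)$ and residual SDs $\sigma_g \sim U(0.4, 0.8)$ emulate log-scale
  array intensities; batch offsets $b_{sg} \sim N(0, 0.5^2)$ per study-gene
  and one multiplicative scale $c_s \sim U(0.8, 1.25)$ per study give the
  location/scale heterogeneity that per-study standardization is meant to
  absorb. Default cohort sizes are 80–200 samples per study with per-study
  tumor fractions U(0.25, 0.85), for the reason given above. Default
  between-study heterogeneity is $\tau^2 = 0.02$ (mild, $I^2 \approx 35\%$
  at these group sizes) — enough to exercise the random-effects machinery
  without leaving the regime where DL confidence intervals hold their
  nominal level.
* **Survival.** Tumor samples only, exponential proportional hazards with
  linear predictor $\sum_g \beta_g z_{gi}$ on tumor-standardized
  expression, plus optional clinical effects (age per decade, male
  indicator, ordinal stage). Baseline median survival 36 months. The
  exponential baseline is the simplest PH-consistent choice and is
  irrelevant to Cox estimation, which conditions it away. Censoring is an
  independent exponential time whose rate is solved numerically
  (`uniroot`) so the expected censored proportion matches the requested
  rate under the heterogeneous hazards.
* **Subgroups and correlation.** Mutation labels are Bernoulli per tumor
  sample at the configured prevalence, with the configured shift (in
  within-group SD units) added to mutant tumors. Correlated gene pairs are
  imposed by a Gaussian copula on the residual noise, so the marginal SMD
  structure is untouched. Chained pairs are applied sequentially in list
  order.
* **Determinism.** One global seed; each study uses a substream seed
  derived from it by a fixed arithmetic rule, so cohorts are reproducible
  and studies are independent.

What the generator does *not* emulate: count noise or probe-level
artifacts (values are continuous log-intensities, as in harmonized
multi-cohort databases), platform-specific gene panels (a uniform random
gene dropout per study is available as a crude stand-in), informative
censoring, and correlated batch structure across genes. Passing tests on
these cohorts therefore demonstrate the statistical machinery —
calibration, recovery, the pooling failure mode — not robustness to every
artifact of real archival data.

## Enrichment

`gsea_preranked()` re-implements the weighted running-sum enrichment
statistic on preranked summary statistics: genes sorted by statistic
descending (ties broken by gene id for determinism), hits increment by
$|s|^p / \sum_{hits} |s|^p$ with $p = 1$, misses decrement by $1/(N-m)$;
the ES is the signed maximal deviation. The permutation null draws
same-size gene sets from the ranked universe; when $\binom{N}{m} \le$
`n_perm` the enumeration is exhaustive instead, which makes tiny cases
exactly reproducible against a brute-force oracle. p-values use the
plus-one estimator against same-sign nulls (so $p \ge 1/(n_\mathrm{perm}+1)$),
NES divides by the mean same-sign null magnitude, and BH adjustment is
applied across sets. Defaults: `n_perm = 10000`, set sizes 5–500. The
multilevel refinement used by `fgsea` for ultra-small p-values is
deliberately out of scope — rankings and leading edges, not $10^{-20}$
p-values, are what the downstream interpretation uses. Survival results
rank by meta z-score, tumor-vs-normal results by summary SMD (both
offered).

## Case-study queries

The query layer reproduces the single-gene follow-up workflow:
`group_difference_meta()` (mutant-vs-WT or histology contrasts via
per-study Hedges' G under the same 10-per-group / 3-study rules),
`gene_pair_correlation_meta()` (Fisher-z pooling over tumor samples),
`clinical_covariate_meta()` (age encoded per decade, gender as a male
indicator, stage as ordinal numeric), `rank_gene()` (minimum-tie ranking,
so a reported "rank 63 of 21,142"-style statement is well defined under
ties), and `forest_data()` for per-study views on the natural scale. Stage
is encoded ordinally only; a per-level dummy encoding was considered and
dropped — it changes the estimand from one slope to level contrasts and
belongs in a bespoke analysis rather than a generic query helper. One
cohort-level caveat demonstrated in `analysis/06_case_queries.R`: marginal
covariate hazard ratios are attenuated relative to the generating
conditional effects when the latent gene-driven risk is strong (Cox
non-collapsibility), so the quality-control reading of those metas is
directional, not quantitative.

## Numerical choices and degenerate inputs

* Cox fits: `survival::coxph`, Efron ties, convergence tightened to
  `eps = 1e-10`, 50 iterations; constant covariates and zero-event studies
  are rejected before fitting.
* Standardization is idempotent to $10^{-12}$; constant genes are masked
  (NA rows plus a logged warning), and masking interacts with the
  inclusion rules simply: a masked gene contributes no estimate.
* DL arithmetic is fully vectorized across genes in `meta_table()` (matrix
  form, NA-aware), and agrees with the per-gene `random_effects_meta()` to
  $10^{-12}$; both are cross-checked against `metafor::rma(method="DL")`
  at $10^{-10}$.
* GSEA null ES values are computed from hit positions only (the running
  sum is piecewise linear between hits), with candidates scanned in list
  order so magnitude ties resolve exactly as the full walk does.
* Benchmark problem sizes used by the tests and acceptance script — 5000
  genes × 8–10 studies for calibration/inflation, 1000 genes for coverage,
  200 replicates for recovery — keep the complete run in the low minutes
  on one CPU while leaving Monte-Carlo error well inside the asserted
  bands.

## Known limitations

* Survival meta-analysis is univariate by design; adjusted or multivariate
  models, time-varying effects and competing risks are out of scope.
* No meta-regression, publication-bias diagnostics or cumulative meta.
* No batch *correction*: the package demonstrates the pooled-analysis
  failure mode and the meta-analytic remedy, it does not implement
  ComBat-style adjustment.
* Gene identifiers are opaque strings; any cross-platform symbol
  harmonization must happen upstream.
* The DL conservativeness at small $k$ described above is inherent to the
  estimator, not fixed here; users needing exact small-$k$ error control
  should use the Knapp–Hartung flag.
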