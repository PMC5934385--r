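---
title: "Candidate-gene pharmacogenetics of antidepressant response: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene pharmacogenetics of antidepressant response: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpgx)
```

## The problem this package addresses

Roughly a third of patients with major depressive disorder do not respond
adequately to SSRI antidepressants, and pharmacogenetic studies try to find
genetic variants that predict who will. `adpgx` implements, as a reusable and
tested pipeline, the standard two-site candidate-gene analysis of
antidepressant treatment response: longitudinal 21-item Hamilton Rating Scale
for Depression (HRSD) assessments are turned into four treatment-response
outcomes, missing follow-ups are multiply imputed, genotypes pass sample- and
marker-level quality control, each marker is tested under an additive model
adjusted for sex and age, genes are tested with an LD-pruned permutation set
test, and the two sites are combined both by Fisher's combined-probability
meta-analysis and by a pooled mega-analysis.

Because the cohorts such studies rest on are not publicly deposited, the
package ships a synthetic-data generator that emulates the design: two
recruitment sites (a 268:187 split of 455 patients), ten candidate genes of
the neurotrophic/BDNF signalling pathway, LD-block genotypes, HRSD
trajectories with a baseline-severity inclusion rule, and a realistic
missing-data pattern mixture. Every stage of the pipeline is exercised end to
end against this generator.

## Phenotype derivation

All four outcomes derive from the HRSD panel (21 items per visit at baseline
and weeks 2, 4, 8; item 1 is "depressed mood", scored 0-4). With `B` the
baseline total and `W` the week-8 total:

* **remitted** — `W <= 7`;
* **%ΔHRSD** (`response_pct`) — `(W - B) / B`, a signed fraction;
* **response** (`response_binary`) — `%ΔHRSD <= -0.50` (a drop of exactly
  50% counts as response);
* **stem-depressed** — week-8 item 1 at 3 or 4 (moderately severe/severe).

The historical clinical coding assigns 2 to the favourable category and 1
otherwise; the package stores both that coding and the favourable 0/1 recode
used in regression (`favourable_to_code12()` converts losslessly). A visit is
missing if and only if all 21 items are missing; partially missing visits are
a contract violation and raise an error.

## Multiple imputation

Missing follow-up visits are imputed on the scale of visit totals by chained
regression: each incomplete timepoint is regressed on the other three totals
plus age and sex among subjects observed at that visit, and missing values
are replaced by proper predictive draws (posterior draws of coefficients and
residual variance plus residual noise), initialised from a baseline-only
model and swept 10 times. Defaults are `m = 30` completed datasets (the
analysis scripts use `m = 5` at demo scale). Imputed totals are rounded and
clipped to `[0, 66]`; item 1 is then the monotone bin of the imputed total so
the stem outcome stays derivable. Imputation is on totals rather than all 21
items jointly because the totals (plus item 1) are sufficient for every
downstream outcome; a 21-dimensional joint model would add variance and no
information the pipeline uses. Downstream single-marker estimates are pooled
with Rubin's rules (`pool_rubin()`): pooled estimate is the mean, total
variance is within + `(1 + 1/m) ×` between, with the standard small-m
degrees-of-freedom adjustment. Pooling is on the coefficient scale, never by
averaging p-values.

## Quality control

Sample level, in order: plate pass rate (fraction of non-missing calls per
plate) must exceed 0.97, strictly; kin pairs at IBS > 0.9 lose the member
with the lower call rate (ties lexicographic); classical MDS on the `1 - IBS`
distance flags samples more than 6 s.d. from the centroid in the first two
axes. Marker level, in order: exact Hardy-Weinberg test p < 1e-4 (the
conditional exact test given allele counts, two-sided by summing
probabilities no larger than the observed table's), missing rate > 0.05,
folded MAF < 0.05 (computed on non-missing calls; exactly 0.05 is retained).
Each removal carries the first failing rule, and `marker_qc()` is idempotent.
The kinship threshold and the order of rules are package choices where the
design was open; both are configurable in `run_config()`.

## Single-marker and gene-based tests

`fit_additive()` regresses each outcome on minor-allele dosage (0/1/2) with
sex and age, linear for `%ΔHRSD` and logistic otherwise, reporting the 1-df
Wald test. Monomorphic markers and separated logistic fits are flagged, not
fitted. Missing dosages are dropped pairwise per marker.

The gene test maps markers to genes with 50 kb flanks (boundaries inclusive),
keeps markers with single-marker p < 0.1, prunes them greedily in ascending-p
order (ties: position, then id) so that every retained pair has r² < 0.5, and
takes the mean squared z over the retained set as the gene statistic — the
aggregation convention of the classical set-based test. Significance comes
from `R` permutations (50,000 by default; 2,000 at demo scale) that shuffle
the phenotype and covariate rows jointly against the genotype rows — this
preserves the genotype LD structure and the covariate-outcome association —
re-running selection and pruning inside every permutation. The empirical
p-value is `(1 + #{perm >= obs}) / (R + 1)`; permutations with an empty
selection score 0, keeping the null exchangeable; an empty observed selection
yields a missing empirical p. No cap is placed on the retained-set size by
default (`set_max` configures one).

Two numerical choices matter here. First, inside the permutation test both
the observed and the permuted per-marker statistics are 1-df *score* tests
against the sex/age null model (fitted once), not per-permutation Wald
refits: the two are asymptotically equivalent, the observed/permuted pair
stays exchangeable, and the whole permutation distribution reduces to a few
matrix products, which is what makes 50,000 permutations practical.
`assoc_scan()` still reports Wald statistics per marker. Second, for the gene
test missing dosages are mean-imputed within marker so the statistic is
defined for every shuffle; at the post-QC missing rate (≤ 5%) the effect is
negligible.

The per-gene "proportion significant" descriptor is the number of mapped
markers with single-marker p < 0.05 over all mapped markers, before selection
and pruning.

## Meta- versus mega-analysis

Per-site p-values are combined with the inverse-Gamma model
(`fisher_combine()`): each p maps to the upper tail of Gamma(α, 1) and the
sum is referred to Gamma(kα, 1); the default shape α = 1 is exactly Fisher's
method, `X = -2 Σ log p ~ χ²(2k)` (for two sites the tail has the closed form
`e^(-X/2)(1 + X/2)`). The combination is direction-blind, so effect-direction
concordance across sites is reported as its own column. Gene-level results
combine the per-site empirical p-values with the same functional — the
combiner is recorded in the output because the convention is not fixed in the
field. The mega-analysis is a single regression on the concatenated sample;
a site indicator is off by default (the two sites are harmonised by
construction) and switchable with `include_site_covariate`.

Reporting tiers are fixed: variants are significant below 5e-4 and suggestive
below 5e-3; genes below 1e-2 and 5e-2. A unit is reported when either the
meta or the mega p passes, and flagged `in_both` when both are below the
suggestive cut. Alongside these fixed tiers, `effective_tests()` reports an
LD-adjusted threshold `0.05 / Meff`, with Meff the number of tags left by
position-ordered greedy pruning at r² ≥ 0.8 — a deliberately simple stand-in
for block-based effective-test estimators, with the threshold configurable.

## The synthetic cohort

`simulate_genotypes()` draws, per gene, a latent normal vector with AR(1)
correlation `block_rho` and thresholds each coordinate at the Hardy-Weinberg
genotype-probability quantiles of the marker's target MAF (a Gaussian
copula). Marginals are therefore exactly Hardy-Weinberg while adjacent
markers carry tunable LD; this gives direct control of the two quantities the
pruning/permutation machinery cares about without haplotype pools,
recombination maps or phasing — which is also what the generator deliberately
does *not* emulate (no haplotype structure, no population admixture, no
genotyping batch effects beyond missingness). Passing tests therefore show
the machinery is correct under controlled MAF/LD/missingness, not that any
cohort-specific biological result is reproduced.

`simulate_hrsd()` gives each subject a baseline total from normal(22, 5)
truncated to `[14, 66]` (the inclusion rule admits only baselines of 14 and
above) and a latent week-8 percentage change `d = -0.46 + Σ β·dosage +
N(0, 0.20)`; intermediate visits interpolate linearly with rounded
normal(0, 2) visit noise, totals clipped to `[0, 66]`. The -0.46 (s.d. 0.20)
improvement matches the summary statistics of 8-week SSRI response in the
kind of cohort emulated; the trajectory between endpoints is the simplest
model satisfying the endpoint definitions, since only endpoints enter the
outcomes. Item 1 is the monotone bin `min(4, floor(total / 5))` of the
concurrent total, and the other 20 items spread the remainder
deterministically — real item-level correlation structure is not emulated.
Genetic effects act on the latent percentage change (all four outcomes derive
from the same trajectory); `case_status` effects instead drive the logistic
case sampler in `simulate_case_control()`. Ages are normal(43.7, 12)
truncated to `[18, 80]` and sex is Bernoulli(0.713 female), matching the
post-QC demographics of the emulated cohort.

`inject_missingness()` assigns each subject one of eight observed/missing
patterns over (baseline, w2, w4, w8) with probabilities 394:10:10:10:1:2:0:1
out of 428 — the pattern mixture of the emulated study, under which 92.06% of
subjects are complete cases and (14, 12, 13) follow-up visits are missing at
weeks 2, 4 and 8 per 428 subjects. Baseline is never masked and observed
values are never altered. All generators take explicit seeds, with pipeline
substreams derived from one master seed (`substream_seed()`).

## Problem sizes and runtime choices

The shipped demonstration (`demo_config()`) uses the full two-site design
(n = 455) over the ten-gene panel at 20 markers per gene, one causal VEGFA
variant with β = +0.08 per allele on %ΔHRSD, m = 5 imputations and R = 2,000
permutations; one end-to-end run takes seconds, and the 20-replicate causal
recovery study (`analysis/07_causal_recovery.R`) a few minutes. The test
suite calibrates the permutation test's type-I error over 500 null cohorts
(n = 400, 20 AR(1) markers, R = 2,000) and checks the exact Hardy-Weinberg
test against full enumeration for every genotype table with up to 50
samples. These sizes were chosen so the whole suite runs comfortably on one
CPU; the statistical conclusions they support (calibration, unbiasedness,
exactness) do not depend on scaling further.

## Degenerate inputs and tie-breaks

Monomorphic markers: flagged in scans, excluded from gene statistics, counted
in `n_total` denominators. Empty gene selections: valid, reported with
missing empirical p. Ties in pruning order: position, then id, so results are
permutation-invariant to input order. Constant covariates: an error, never a
silent drop. p-values of exactly 0 or above 1 are rejected by
`fisher_combine()`; empirical p-values are bounded below by `1/(R + 1)` by
construction.

## Known limitations

* No genotype imputation against reference panels, no phasing, no
  genome-build liftover; genotypes enter as called dosages.
* The generator's LD is a stationary AR(1) copula per gene — adequate for
  testing pruning and permutation machinery, not a model of real haplotype
  blocks.
* Gene-level meta-analysis combines empirical p-values whose resolution is
  bounded by `1/(R + 1)`; with few permutations the combined p is
  correspondingly coarse.
* The permutation test assumes exchangeability of subjects under the null
  within the analysed stratum; strong population structure would require
  stratified permutation, which is not implemented.
* Case-control support covers harmonised dosage tables and logistic scans;
  it does not attempt allele-frequency-based strand resolution beyond
  explicit metadata checks.
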