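---
title: "Methods: combined BRCA1/2 diagnostics and the BRCAness methylation classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined BRCA1/2 diagnostics and the BRCAness methylation classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brcadx)
```

## Scope

`brcadx` models the three layers of BRCA1/2 assessment used to decide
PARP-inhibitor (PARPi) eligibility in high-grade serous ovarian carcinoma:

1. **Sequence variants** — tiered somatic calls (AMP/CAP Tier 1/2 =
   clinically significant, Tier 3 = VUS) consumed as annotations, filtered
   by alternate allele fraction, and run through the reporting rules.
2. **Copy number** — read-depth calling of whole-gene and sub-gene events
   on a 37-gene hereditary-cancer capture panel.
3. **Promoter methylation** — calling BRCA1/2 promoter hypermethylation
   from array beta values, and, genome-wide, a "BRCAness" classifier that
   scores the methylation profile associated with BRCA1/2 deficiency.

Everything upstream of these representations (alignment, variant calling,
tier assignment, array normalization, IDAT parsing) is out of scope; inputs
enter as tables and matrices. Because the underlying patient data are not
deposited, the package ships seeded generators that emulate the study
conditions with known truth, so every stage is testable end to end.

## Eligibility rules

A sample is PARPi-eligible when it carries (in priority order of the
recorded basis):

* a BRCA1/2 Tier 1 or Tier 2 sequence variant,
* a loss-of-function CNV — a full-gene deletion, an intragenic deletion, or
  a curated truncating intragenic duplication (the BRCA1 exon-13
  duplication); whole-gene duplications are never eligible because they are
  not established to disrupt recombination repair, or
* a positive promoter hypermethylation call (flagged as its own basis).

The reporting allele-fraction filter retains variants with AF strictly
above 10%. A footnoted caution applies to samples whose qualifying
variants all sit at AF ≤ 40%: tumor content may be low. We implement the
40% remark as an advisory note rather than a hard gate, because reported
Tier 1 carriers below that fraction exist in the transcribed table (the
hash-marked low-tumor samples); `af_gate = TRUE` switches to gating.

Counting in `summarize_cohort()` is per sample, never per variant, and
"VUS-only" means: at least one Tier 3 variant, no Tier 1/2 variant, and no
CNV record for that sample.

## CNV calling

Depths are normalized in two steps: each sample is divided by its own
median target depth (library size), then each target by the mean
library-corrected value across the whole-blood reference population. An
unaffected diploid target then has expectation 1, and the scheme is exactly
invariant to per-sample depth scaling. The reference algorithm this
reconstructs is not published in detail; the two-step scheme is our
documented reconstruction, and targets with a zero reference mean are
masked and reported.

Whole-gene events are called by concordance across four parameters per
sample–gene: the raw mean normalized value, the intra-sample ratio (gene
mean over the mean of the other 36 genes' means), and two inter-sample
ratios (against the other FFPE samples and against the whole-blood
controls, index sample excluded). Mapping the minimum allelic fraction
`f = 0.30` to depth assumes a diploid background: a deletion at fraction
`f` scales depth by `1 - f/2`, a duplication by `1 + f/2`, so the deletion
threshold is a ratio of 0.85 and the duplication threshold 1.15, both
inclusive. The estimated allelic fraction is `2|1 - r|` with `r` the
median of the three ratio parameters. Concordance defaults to
all-four-agree; a `three_of_four` switch relaxes it.

Two numerical choices matter in small cohorts:

* **Inter-sample centering.** Whether the original normalization used a
  mean or a median is unstated, so both are exposed. The default is the
  median, because with a mean a second event carrier in the denominator
  cohort drags the ratio toward 1 and costs sensitivity; in a
  172-sample cohort the difference is negligible, in a 16-sample simulated
  cohort it is not.
* **Raw-value baseline.** The `raw_value` criterion compares against a 20%
  trimmed mean of the gene's raw values across the FFPE cohort, robust to
  the event carriers themselves.

Sub-gene events use the 50%-deviation rule: a contiguous exon run is called
when its mean deviates by at least 50% (ratio ≤ 0.5 or ≥ 1.5, inclusive)
from the mean of the remaining exons. Candidate runs are restricted to at
most half the gene, so the "remainder" being compared against is always
the majority — without this restriction the complement of every true event
is also a candidate, and single-exon denominators generate spurious calls.
Among qualifying runs the maximal deviation (|log2 ratio|) wins; ties
prefer the longer run, then the earlier start.

## Methylation QC

Beta values are `M / (M + U + offset)`. The literal definition has no
offset; the default offset of 100 is the standard stabilizer for
low-intensity probes, and `offset = 0` reproduces the plain ratio (with
the 0/0 case defined as 0 and logged). Probe exclusion follows four rules:
detection p-value above 0.1 (strictly; the scope defaults to
"fails in any sample" to keep the matrix rectangular, with per-sample
masking switchable), chromosomes X/Y, SNP at the CpG or extension base,
and known cross-reactivity. Filtering is a pure selection — retained
values are untouched — and therefore idempotent; removal counts are
reported per rule and deduplicated.

Genome-wide bimodality is operationalized as the fraction of betas in the
open mid-band (0.3, 0.7), passing below 0.5. A formal dip test would add a
dependency and an asymptotic approximation for what is, in practice, a
gross-failure screen; the mass statistic is fully specified and testable.
It requires at least 1000 probes. Sample outliers are screened by
projecting onto the top principal components of the probe-centered matrix
and flagging robust z-scores (median/MAD per component) beyond 3 by
default; at cohort sizes near 80 a 3-SD cut admits occasional chance
flags, which is why the threshold is exposed. With two batches the
centroid separation per component is reported in pooled-SD units.

## Promoter calling

A promoter call is the median beta across a region's member probes
(R's midpoint convention for even counts; at least 3 probes required).
Status uses two thresholds: below 0.15 is hypomethylated — the fully
unmethylated state observed in intact promoters — and at or above 0.30 is
hypermethylated. The gain observed in positive tumors is monoallelic,
reaching region medians near 0.6, so 0.30 sits at the midpoint boundary
between "clearly silent" and "monoallelic gain"; no printed cut-off
exists, so the value is config-exposed. The band between the thresholds is
an explicit indeterminate zone flagged for review rather than forced into
either call. Samples carrying a reportable Tier 1/2 variant are expected
not to be hypermethylated; a violation raises a warning, not an error.

## The BRCAness classifier

Feature selection has three steps, computed on training data only:

1. keep probes with absolute group-mean beta difference strictly above
   0.05;
2. rank by AUC (Mann–Whitney with midrank ties) and keep the top 1000. The
   ranking statistic defaults to `max(AUC, 1 - AUC)` so hypo- and
   hypermethylated markers compete symmetrically; the literal
   greatest-AUC behaviour is a switch;
3. walk the ranked list and drop any probe whose squared Pearson
   correlation with an already-kept probe exceeds 0.8 within either class
   (cases and controls computed separately; requiring both is a switch).
   Greedy descending-AUC order keeps the stronger probe of each correlated
   pair, and the full pruning log (probe, partner, class, R²) is returned.

Six base learners are fitted on standardized training features
(training-set statistics only): elastic-net logistic regression
(mixing 0.5, penalty by internal cross-validation), linear- and RBF-kernel
SVMs (cost 1, RBF bandwidth 1/p, Platt probabilities), a linear
discriminant fitted on the top principal components (k = min(10, n-2) —
LDA itself is singular when p ≥ n), a random forest (300 trees), and a
Gaussian-prior MAP logistic model (ridge penalty 0.05). Hyperparameters
are fixed defaults with no outer tuning. Every learner emits a
probability-like score in [0, 1].

The ensemble follows the stacked-generalization construction: base
predictions are generated out-of-sample by an internal stratified 5-fold
split of the training partition, and an L1-penalized regression of the
labels on those six columns with non-negative coefficients assigns the
weights, renormalized to sum to 1. Exactly identical prediction columns
are collapsed onto the first occurrence, which makes the tie-break
deterministic; if the selected penalty zeroes every coefficient, the
single learner with the best internal AUC gets weight 1 (flagged
fallback).

Evaluation is stratified random 5-fold cross-validation. Plain random
folds at n = 80 risk single-class folds; stratification is a documented
deviation from a literal random split. Within every fold, feature
selection and all fitting see only the training folds — the leakage guard
in the test suite replaces a fold's test samples with noise and verifies
the selected features do not change. Metrics are confusion-matrix
accuracy/sensitivity/specificity/PPV/NPV at threshold 0.5 plus rank-based
AUC; undefined cells (no positive predictions) are reported missing, never
NaN-propagated, and fold averages are arithmetic means computed before
rounding. Printed two-decimal values use R's default rounding
(half-to-even), which reproduces, e.g., 0.625 → 0.62 for a
9-positive/7-negative fold.

## What the generators emulate — and what they do not

**Methylation cohorts** (`simulate_methylation_cohort`): 44 positive and
36 negative samples over 10,000 probes by default, 200 of them
informative with a planted group difference of 0.15. Marginals are beta
distributed around per-probe baselines drawn from a bimodal prior (45%
hypomethylated, 45% hypermethylated, 10% intermediate) with concentration
50; informative probes take baselines in the mid-range and a random
gain/loss direction, means clamped to [0.02, 0.98] with clamping recorded.
Correlation enters through a Gaussian copula: probes within a block of 10
share a per-sample latent factor with loading 0.95, so within-group
pairwise R² inside a block is about 0.9 — emulating co-methylated regions
— while marginals stay exactly beta. Informative probes fill whole blocks,
so correlation pruning competes signal probes against their block-mates as
it does in real co-methylated promoters. The generator does not emulate:
cell-type composition, tumor purity gradients, probe-type chemistry
differences, batch effects (unless you add them), or genomic
autocorrelation beyond the block structure. A perfect cross-validated AUC
on these cohorts therefore demonstrates correct, leakage-free mechanics —
not the accuracy attainable on tissue data, where the published
operating point is far from perfect.

**Coverage cohorts** (`simulate_coverage_cohort`): negative-binomial
depths around per-target efficiencies (log-normal, sd 0.3) times
per-sample library factors (log-normal, sd 0.15) at 500x mean depth, 37
genes × 10 targets. Dispersion 400 gives a per-target CV near 7%, the
precision a clinically validated read-depth CNV assay operates at; lower
it to emulate degraded FFPE libraries. Spiked events scale expected depth
by `1 ± f/2`. Whole-blood controls never carry events.

**Promoter cohorts** (`simulate_promoter_cohort`): 38 screened samples by
default with 2 spiked monoallelic gains; background promoter probes have
means in [0.03, 0.10] (region medians below 0.15), spiked samples draw a
region mean in [0.48, 0.58] so realized medians stay inside the reported
[0.45, 0.60] gain band and clear of the indeterminate zone — which is why
the caller's sensitivity and specificity are exactly 1 on the default
synthetic cohort.

All generators pin the RNG (Mersenne-Twister, inversion normals,
rejection sampling) and restore the caller's RNG state, so a fixed seed
gives bit-identical output across platforms. Independent cohorts derived
from one master seed use the splitting rule
`(seed + 1000003 k) mod (2^31 - 1)`.

## Packaged tables

The transcribed reportable-variant table ships with a `source` column
because the extracted table text loses column boundaries: `table` rows are
direct transcription, `reconciled` rows carry a tier assignment forced by
the published per-category counts, one `results_text` row adds the fourth
BRCA1 full-gene deletion that the results prose states but the printed
table lacks, and two `table_unreconciled` rows cannot be reconciled with
the stated counts at all and are excluded by default (the loader returns
them separately rather than resolving the discrepancy silently). The
fold-metric table keeps the printed average column alongside recomputed
means; they agree within 0.005 on every row.

## Problem sizes used by the test suite

The suite exercises the full study condition where the property demands it
(planted-signal recovery: 10,000 probes, 80 samples, effect 0.15, five
seeds) and scaled-down cohorts (2,000 probes, three seeds) for the
null-label and effect-monotonicity properties, whose validity does not
depend on probe count. CNV recall uses twenty 16-sample cohorts with
deletions spiked at fractions 0.4/0.6/1.0. The whole suite and the
acceptance script each run in well under five minutes on one CPU.

## Known limitations

* Tier assignment, germline-vs-somatic status, and zygosity are out of
  scope by design; tiers are consumed as annotations.
* The CNV caller does not segment across genes and has no allele-fraction
  (BAF) model; its fraction estimate assumes a diploid background.
* The promoter caller does not deconvolve tumor purity; a low-purity
  monoallelic gain can land in the indeterminate zone.
* Classifier metrics on synthetic cohorts saturate; they validate the
  pipeline's mechanics and invariants, not clinical accuracy.
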