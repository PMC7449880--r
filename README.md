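# brcadx

Combined BRCA1/2 diagnostics for high-grade serous ovarian carcinoma:
sequence-variant reporting, read-depth copy-number calling, promoter
methylation calling, and a genome-wide methylation "BRCAness" classifier.

## The problem

PARP-inhibitor therapy targets tumors with deficient homologous
recombination repair, most prominently BRCA1/2-deficient ovarian cancer.
Eligibility testing that looks only at sequence variants misses two other
routes to the same deficiency: loss-of-function copy-number variants and
epigenetic silencing by promoter hypermethylation. `brcadx` implements the
full multi-assay workflow for a molecular diagnostics setting — each assay
as reusable functions, the eligibility rules that combine them, and the
cumulative diagnostic-yield accounting — plus a classifier that asks
whether the genome-wide DNA methylation profile itself predicts
"BRCAness". Since the underlying patient-level data are not public, the
package also ships seeded synthetic-data generators with known truth, so
every stage is verifiable end to end.

## Methods at the core

* **Eligibility rules** — a sample qualifies via a Tier 1/2 BRCA1/2
  variant (allele fraction > 10%), a loss-of-function CNV (full-gene
  deletion or truncating intragenic duplication; whole-gene duplications
  never qualify), or BRCA1/2 promoter hypermethylation, in that basis
  priority.
* **CNV calling** — depths are normalized by sample median and a
  whole-blood reference population, then a whole-gene event at allelic
  fraction f ≥ 0.30 must show concordance across four parameters (raw
  gene value, intra-sample ratio, FFPE and whole-blood inter-sample
  ratios) at the diploid thresholds 1 − f/2 (deletion) / 1 + f/2
  (duplication); sub-gene events need a ≥ 50% deviation of a contiguous
  exon run from the remainder of the gene. Estimated fraction: 2·|1 − r|
  for the median ratio r.
* **Methylation QC** — β = M/(M + U + offset); probes fail on detection
  p > 0.1, X/Y location, SNP at the interrogation/extension base, or
  cross-reactivity; samples are checked for genome-wide bimodality and
  PCA outliers.
* **Promoter calling** — median β across the promoter region: < 0.15
  hypomethylated, ≥ 0.30 hypermethylated (monoallelic gain reaches
  ~0.6), in between flagged indeterminate.
* **BRCAness classifier** — per-fold feature selection (|Δβ̄| > 0.05 →
  top-1000 by Mann–Whitney AUC → greedy within-class R² > 0.8 pruning),
  six base learners (elastic net, linear/RBF SVM, LDA on principal
  components, random forest, Gaussian-prior MAP logistic), stacked by a
  non-negative lasso on internally cross-validated predictions, evaluated
  by leakage-free stratified fivefold cross-validation reporting
  accuracy, sensitivity, specificity, PPV, NPV and AUC per fold and
  averaged.

## Worked example

```r
library(brcadx)

# 1. the packaged reportable-variant table, filtered and summarized
tab1     <- load_table1_fixture()
variants <- filter_by_allele_fraction(tab1$variants, 0.10)
summarize_cohort(variants, tab1$cnvs)
#> Cohort summary
#>   samples with >=1 Tier 1/2 variant : 36
#>   samples with >=1 Tier 1 variant   : 27 (BRCA1 15 / BRCA2 12)
#>   Tier 2-only samples               : 9
#>   VUS-only samples                  : 6
#>   loss-of-function CNV samples      : 9
#>   any CNV per gene                  : BRCA1 10 / BRCA2 11

# 2. promoter screen of 38 sequence-negative samples (2 spiked gains)
pc     <- simulate_promoter_cohort(n_neg = 38, n_hyper = 2, seed = 1)
screen <- screen_promoters(pc)
screen
#> Promoter methylation screen
#>        status
#> gene    hypomethylated indeterminate hypermethylated
#>   BRCA1             36             0               2
#>   BRCA2             38             0               0
#> hypermethylated calls: 2

# 3. cumulative diagnostic yield across the three assays
calls <- classify_cohort_eligibility(variants, tab1$cnvs,
                                     promoter_calls = screen$calls)
cumulative_yield(calls, n_total = tab1$cohort_size)
#> Diagnostic yield (n = 172)
#>   sequence variants       : 36 (20.9%)
#>   LOF CNV only            : 9 (5.2%)
#>   promoter methylation only: 2 (1.2%)
#>   cumulative              : 47 (27.3%)

# 4. the BRCAness classifier on a synthetic labelled cohort
cohort <- simulate_methylation_cohort(
  sim_config(seed = 1, n_probes = 2000, n_informative = 100))
cross_validate(cohort, seed = 1)
#> Cross-validation report (5 folds)
#>                  Fold 1 Fold 2 Fold 3 Fold 4 Fold 5 Average
#> Overall accuracy      1      1      1      1      1       1
#> ...
```

Reading the numbers: 36 of 172 tumors (20.9%) carry a clinically
significant sequence variant; loss-of-function CNVs add 9 samples and
promoter hypermethylation another 2, lifting the cumulative yield to
47/172 (27.3%). The classifier separates the synthetic cohort perfectly —
the planted signal (effect 0.15 at 100 probes) is strong by design; what
the cross-validation demonstrates is that selection and fitting are
leakage-free, not the accuracy attainable on tissue data.

The full pipeline (`run_pipeline(demo_config())`) chains all stages and
writes TSV reports plus a run log; `inst/cli/brcadx.R` exposes the same
stages as shell subcommands.

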