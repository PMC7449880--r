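# Generators: shapes, determinism, planted-effect recovery, correlation
# structure, and the packaged table fixtures.

test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(n_informative = 50, n_probes = 20), "n_informative")
  expect_error(sim_config(effect_delta = 1.2), "effect_delta")
  expect_error(sim_config(tumor_fraction = 1.5), "tumor_fraction")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(n_pos = 0), "n_pos")
})

test_that("methylation cohort has the configured shape, range and truth", {
  cohort <- simulate_methylation_cohort(sim_config(seed = 1))
  expect_equal(dim(cohort$betas), c(10000L, 80L))
  expect_length(cohort$truth$informative_probes, 200L)
  expect_true(all(cohort$betas >= 0 & cohort$betas <= 1))
  expect_equal(sum(cohort$labels == "positive"), 44L)
  expect_equal(sum(cohort$labels == "negative"), 36L)

  # planted-effect recovery: probe-averaged group difference near delta
  pos <- cohort$labels == "positive"
  inf <- cohort$truth$informative_probes
  d <- rowMeans(cohort$betas[inf, pos]) - rowMeans(cohort$betas[inf, !pos])
  expect_lt(abs(mean(abs(d)) - 0.15), 0.03)

  # correlated blocks: median within-group pairwise R^2 above 0.8
  b1 <- names(cohort$truth$block_of)[
    cohort$truth$block_of == cohort$truth$informative_blocks[1]]
  r2 <- cor(t(cohort$betas[b1, pos]))^2
  expect_gt(median(r2[lower.tri(r2)]), 0.8)

  # determinism: bitwise identical rerun
  again <- simulate_methylation_cohort(sim_config(seed = 1))
  expect_identical(cohort$betas, again$betas)
  expect_identical(cohort$truth, again$truth)
})

test_that("null effect size yields no group separation at informative probes", {
  cohort <- simulate_methylation_cohort(
    sim_config(seed = 2, n_probes = 2000, n_informative = 200,
               effect_delta = 0))
  pos <- cohort$labels == "positive"
  inf <- cohort$truth$informative_probes
  d <- rowMeans(cohort$betas[inf, pos]) - rowMeans(cohort$betas[inf, !pos])
  expect_lt(abs(mean(d)), 0.02)
})

test_that("coverage cohort reflects spiked events through depth ratios", {
  cfg <- sim_config(seed = 5, n_samples_cov = 12)
  ev <- data.frame(sample = c(1, 2), gene = c("BRCA1", "BRCA2"),
                   event = "deletion", fraction = c(1.0, 0.3))
  cov <- simulate_coverage_cohort(cfg, events = ev)
  expect_true(all(cov$depths >= 0))
  expect_true(all(cov$depths == round(cov$depths)))

  nm <- normalize_coverage(cov)
  g1 <- cov$targets$gene == "BRCA1"
  g2 <- cov$targets$gene == "BRCA2"
  expect_lt(abs(mean(nm["FFPE_01", g1]) - 0.5), 0.075)   # 1 - 1.0/2
  expect_lt(abs(mean(nm["FFPE_02", g2]) - 0.85), 0.075)  # 1 - 0.3/2

  # no spike: all four parameters near 1 for every gene of a clean sample
  p <- lapply(unique(cov$targets$gene)[1:5], function(g) {
    compute_cnv_parameters(nm, cov$targets, "FFPE_05", g)
  })
  vals <- unlist(lapply(p, function(x) {
    c(x$raw_value, x$intra_ratio, x$ffpe_inter_ratio, x$wb_inter_ratio)
  }))
  expect_true(all(vals > 0.9 & vals < 1.1))

  # determinism
  again <- simulate_coverage_cohort(cfg, events = ev)
  expect_identical(cov$depths, again$depths)
})

test_that("coverage simulation validates events and depth", {
  cfg <- sim_config(seed = 1, n_samples_cov = 4)
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(
    simulate_coverage_cohort(cfg, events = data.frame(
      sample = 1, gene = "NOSUCH", event = "deletion")),
    "panel genes")
  expect_error(
    simulate_coverage_cohort(cfg, events = data.frame(
      sample = 99, gene = "BRCA1", event = "deletion")),
    "FFPE")
})

test_that("promoter cohort plants the configured number of gains", {
  pc <- simulate_promoter_cohort(n_neg = 38, n_hyper = 2, seed = 1)
  b1 <- pc$probe_regions$probe_id[pc$probe_regions$gene == "BRCA1"]
  med <- apply(pc$betas[b1, ], 2, median)
  expect_equal(sum(med >= 0.45), 2L)
  expect_true(all(med[setdiff(names(med),
                              pc$truth$hypermethylated_samples)] < 0.15))
  expect_true(all(med[pc$truth$hypermethylated_samples] >= 0.45 &
                  med[pc$truth$hypermethylated_samples] <= 0.60))

  # no spikes, and exact reproducibility
  pc0 <- simulate_promoter_cohort(n_neg = 10, n_hyper = 0, seed = 2)
  expect_length(pc0$truth$hypermethylated_samples, 0L)
  again <- simulate_promoter_cohort(n_neg = 38, n_hyper = 2, seed = 1)
  expect_identical(pc$betas, again$betas)
  expect_error(simulate_promoter_cohort(n_neg = 5, n_hyper = 6), "exceed")
})

test_that("reportable-variant fixture parses into validated records", {
  tab1 <- load_table1_fixture()
  rec <- tab1$variants[tab1$variants$sample_id == "1105-054", ]
  expect_equal(rec$gene, "BRCA1")
  expect_equal(rec$hgvs_c, "c.5266dupC")
  expect_equal(rec$tier, 1L)
  expect_equal(rec$allele_fraction, 0.584)

  s <- summarize_cohort(tab1$variants, tab1$cnvs)
  expect_equal(s$n_tier12_samples, 36L)
  expect_equal(s$n_vus_only_samples, 6L)
  expect_equal(tab1$cohort_size, 172L)

  # unreconciled rows are excluded by default but reported
  expect_equal(nrow(tab1$unreconciled_variants), 2L)
  expect_false(any(tab1$variants$source == "table_unreconciled"))
  all_rows <- load_table1_fixture(include_unreconciled = TRUE)
  expect_equal(nrow(all_rows$variants),
               nrow(tab1$variants) + 2L)
})

test_that("malformed fixtures raise errors naming the offending row", {
  dir <- withr::local_tempdir()
  tab1 <- load_table1_fixture()
  bad <- tab1$variants
  bad$tier[3] <- 7L
  write.table(bad, file.path(dir, "table1_variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tab1$cnvs, file.path(dir, "table1_cnvs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_table1_fixture(path = dir), "row 3")

  bad2 <- tab1$cnvs
  bad2$exons[3] <- 5   # full-gene event must not carry an interval
  write.table(tab1$variants, file.path(dir, "table1_variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bad2, file.path(dir, "table1_cnvs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_table1_fixture(path = dir), "row 3")
})

test_that("cross-validation metric fixture exposes folds and averages", {
  rep2 <- load_table2_fixture()
  expect_s3_class(rep2, "cv_report")
  expect_equal(nrow(rep2$folds), 5L)
  expect_equal(rep2$folds$accuracy[1], 0.69)
  expect_equal(rep2$folds$auc[5], 0.78)
  printed <- attr(rep2, "printed_average")
  expect_named(printed, c("accuracy", "sensitivity", "specificity",
                          "ppv", "npv", "auc"))
})
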