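# Coverage normalization, the four concordance parameters, whole-gene and
# sub-gene calling.

make_flat_cohort <- function(depth = 500, n_ffpe = 3, n_wb = 2,
                             genes = c("BRCA1", "BRCA2", "ATM"), tpg = 4) {
  targets <- data.frame(
    target_id = sprintf("%s_t%d", rep(genes, each = tpg),
                        rep(seq_len(tpg), length(genes))),
    gene = rep(genes, each = tpg), exon = rep(seq_len(tpg), length(genes)),
    stringsAsFactors = FALSE
  )
  ids <- c(sprintf("F%d", seq_len(n_ffpe)), sprintf("W%d", seq_len(n_wb)))
  depths <- matrix(depth, length(ids), nrow(targets),
                   dimnames = list(ids, targets$target_id))
  list(depths = depths, targets = targets,
       samples = data.frame(sample_id = ids,
                            tissue = rep(c("FFPE", "whole_blood_control"),
                                         c(n_ffpe, n_wb))))
}

test_that("normalization yields 1 for a uniform cohort and cancels library size", {
  cc <- make_flat_cohort()
  nm <- normalize_coverage(cc$depths, cc$samples$tissue)
  expect_true(all(nm == 1))

  cc$depths["F1", ] <- 1000  # 2x library of a flat sample
  nm2 <- normalize_coverage(cc$depths, cc$samples$tissue)
  expect_true(all(nm2 == 1))

  expect_error(normalize_coverage(cc$depths, rep("FFPE", 5)),
               "whole-blood")
})

test_that("zero-reference targets are masked and reported", {
  cc <- make_flat_cohort()
  cc$depths[4:5, "ATM_t1"] <- 0  # both controls dead on one target
  nm <- normalize_coverage(cc$depths, cc$samples$tissue)
  expect_equal(attr(nm, "masked_targets"), "ATM_t1")
  expect_true(all(is.na(nm[, "ATM_t1"])))
})

test_that("concordance parameters respond to a spiked deletion as 1 - f/2", {
  cfg <- sim_config(seed = 21, n_samples_cov = 12)
  ev <- data.frame(sample = 1, gene = "BRCA1", event = "deletion",
                   fraction = 0.5)
  cov <- simulate_coverage_cohort(cfg, events = ev)
  nm <- normalize_coverage(cov)
  p <- compute_cnv_parameters(nm, cov$targets, "FFPE_01", "BRCA1")
  expect_lt(abs(p$intra_ratio - 0.75), 0.05)
  expect_lt(abs(p$wb_inter_ratio - 0.75), 0.05)

  # a global 2x library shift changes no parameter
  cov$depths["FFPE_01", ] <- 2L * cov$depths["FFPE_01", ]
  nm2 <- normalize_coverage(cov)
  p2 <- compute_cnv_parameters(nm2, cov$targets, "FFPE_01", "BRCA1")
  expect_equal(p2$intra_ratio, p$intra_ratio, tolerance = 1e-10)
  expect_equal(p2$wb_inter_ratio, p$wb_inter_ratio, tolerance = 1e-10)
})

test_that("whole-gene calls are boundary-inclusive and need full concordance", {
  mk <- function(raw, intra, ffpe, wb) {
    structure(list(sample = "s", gene = "BRCA1", raw_value = raw,
                   intra_ratio = intra, ffpe_inter_ratio = ffpe,
                   wb_inter_ratio = wb), class = "cnv_params")
  }
  # all ratios exactly at the deletion boundary: called, fraction 0.30
  call <- call_whole_gene(mk(0.85, 0.85, 0.85, 0.85), raw_baseline = 1)
  expect_equal(call$event, "full_deletion")
  expect_equal(call$estimated_allelic_fraction, 0.30)

  expect_equal(call_whole_gene(mk(1, 1, 1, 1), raw_baseline = 1)$event,
               "none")
  # discordant: one parameter at 1 blocks the call
  expect_equal(
    call_whole_gene(mk(0.7, 0.7, 0.7, 1.0), raw_baseline = 1)$event,
    "none")
  # three-of-four relaxation admits it
  expect_equal(
    call_whole_gene(mk(0.7, 0.7, 0.7, 1.0), raw_baseline = 1,
                    concordance = "three_of_four")$event,
    "full_deletion")
  # duplication side is symmetric
  expect_equal(
    call_whole_gene(mk(1.2, 1.2, 1.2, 1.2), raw_baseline = 1)$event,
    "full_duplication")
})

test_that("sub-gene runs are called at 50% deviation, boundaries inclusive", {
  v <- rep(1, 10); names(v) <- 1:10
  v[5] <- 1.5
  call <- call_subgene(v, "s", "BRCA1")
  expect_equal(call$event, "exon_duplication")
  expect_equal(call$exons, "5-5")

  expect_equal(call_subgene(rep(1, 10), "s", "BRCA1")$event, "none")

  v2 <- rep(1, 10); names(v2) <- 1:10
  v2[3:4] <- 0.49
  call2 <- call_subgene(v2, "s", "BRCA1")
  expect_equal(call2$event, "exon_deletion")
  expect_equal(call2$exons, "3-4")

  v3 <- rep(1, 10); names(v3) <- 1:10
  v3[7] <- 0.5  # exactly the boundary ratio
  expect_equal(call_subgene(v3, "s", "BRCA1")$event, "exon_deletion")

  expect_error(call_subgene(c(1, 1), "s", "BRCA1"), ">= 3")
})

test_that("calls are invariant to per-sample depth scaling", {
  cfg <- sim_config(seed = 22, n_samples_cov = 10)
  ev <- data.frame(sample = 2, gene = "BRCA2", event = "deletion",
                   fraction = 0.6)
  cov <- simulate_coverage_cohort(cfg, events = ev)
  before <- call_cnvs(cov)$calls
  cov$depths["FFPE_02", ] <- 3L * cov$depths["FFPE_02", ]
  after <- call_cnvs(cov)$calls
  expect_equal(before$event, after$event)
  expect_equal(before$sample_id, after$sample_id)
  expect_equal(before$estimated_allelic_fraction,
               after$estimated_allelic_fraction, tolerance = 1e-10)
})

test_that("sub-threshold fractions stay silent in expectation", {
  cfg <- sim_config(seed = 23, n_samples_cov = 10)
  ev <- data.frame(sample = 1, gene = "BRCA1", event = "deletion",
                   fraction = 0.2)  # expected ratio 0.9, above 0.85
  cov <- simulate_coverage_cohort(cfg, events = ev)
  nm <- normalize_coverage(cov)
  p <- compute_cnv_parameters(nm, cov$targets, "FFPE_01", "BRCA1")
  call <- call_whole_gene(p, raw_baseline =
                            gene_raw_baseline(nm, cov$targets, "BRCA1"))
  expect_equal(call$event, "none")
})

test_that("exon-13 duplication spike is recovered by the sub-gene scan", {
  cfg <- sim_config(seed = 24, n_samples_cov = 10)
  ev <- data.frame(sample = 1, gene = "BRCA1", event = "duplication",
                   fraction = 1.0, exons = "3")
  cov <- simulate_coverage_cohort(cfg, events = ev)
  calls <- call_cnvs(cov)$calls
  hit <- calls[calls$sample_id == "FFPE_01" & calls$gene == "BRCA1", ]
  expect_equal(hit$event, "exon_duplication")
  expect_equal(hit$exons, "3-3")
})
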