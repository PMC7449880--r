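# Beta computation, probe exclusion rules, bimodality and PCA checks.

test_that("beta values follow M / (M + U + offset)", {
  expect_equal(compute_beta(1000, 0, offset = 0), 1.0)
  expect_equal(compute_beta(500, 500, offset = 0), 0.5)
  expect_equal(compute_beta(300, 700, offset = 100), 300 / 1100)
  expect_warning(z <- compute_beta(0, 0, offset = 0), "zero total")
  expect_equal(z, 0)
  expect_error(compute_beta(-1, 5), "non-negative")

  # monotone increasing in M, decreasing in U
  m <- seq(0, 2000, by = 100)
  expect_true(all(diff(compute_beta(m, 500)) > 0))
  expect_true(all(diff(compute_beta(500, m)) < 0))
})

test_that("each exclusion rule removes its probe and counts are reported", {
  probes <- c("p_clean", "p_detp", "p_sex", "p_snp", "p_xr")
  b <- toy_beta_matrix(rep(0.5, 10), probes, c("s1", "s2"))
  ann <- data.frame(
    probe_id = probes,
    chromosome = c("1", "2", "X", "3", "4"),
    snp_at_cpg_or_extension = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    cross_reactive = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  detp <- toy_beta_matrix(c(0.01, 0.01,  0.01, 0.2,  0.01, 0.01,
                            0.01, 0.01,  0.01, 0.01),
                          probes, c("s1", "s2"))
  out <- qc_filter_probes(b, ann, detection_p = detp)
  expect_equal(rownames(out), "p_clean")
  removed <- attr(out, "qc_removed")
  expect_equal(unname(removed$per_rule),
               c(1L, 1L, 1L, 1L))
  expect_equal(removed$total, 4L)

  # values of retained probes are untouched (pure selection)
  expect_equal(out["p_clean", ], b["p_clean", ])
})

test_that("detection p at exactly the threshold is retained, and filtering is idempotent", {
  probes <- sprintf("p%d", 1:3)
  b <- toy_beta_matrix(runif(6), probes, c("s1", "s2"))
  ann <- data.frame(probe_id = probes, chromosome = "1",
                    snp_at_cpg_or_extension = FALSE,
                    cross_reactive = FALSE)
  detp <- toy_beta_matrix(c(0.1, 0.1, 0.05, 0.1, 0.11, 0.02),
                          probes, c("s1", "s2"))
  out <- qc_filter_probes(b, ann, detection_p = detp)
  expect_equal(rownames(out), c("p1", "p2"))  # p == 0.1 kept, 0.11 dropped

  # idempotence and all-clean identity
  out2 <- qc_filter_probes(out, ann)
  expect_equal(unclass(out2)[, ], unclass(out)[, ])
  expect_equal(attr(out2, "qc_removed")$total, 0L)

  expect_error(qc_filter_probes(b, ann[-1, ]), "unannotated")
})

test_that("a probe violating several rules is deduplicated in the total", {
  probes <- c("multi", "clean")
  b <- toy_beta_matrix(rep(0.4, 4), probes, c("s1", "s2"))
  ann <- data.frame(probe_id = probes, chromosome = c("X", "1"),
                    snp_at_cpg_or_extension = c(TRUE, FALSE),
                    cross_reactive = c(TRUE, FALSE))
  out <- qc_filter_probes(b, ann)
  removed <- attr(out, "qc_removed")
  expect_equal(removed$total, 1L)
  expect_equal(sum(removed$per_rule), 3L)  # per-rule counts overlap
})

test_that("bimodality statistic separates bimodal from mid-heavy profiles", {
  set.seed(1)
  bimodal <- c(rbeta(900, 0.5, 10), rbeta(900, 10, 0.5), runif(200, .3, .7))
  res <- bimodality_check(bimodal)
  expect_true(res$pass)

  flat_mid <- rep(0.5, 2000)
  res2 <- bimodality_check(flat_mid)
  expect_false(res2$pass)
  expect_equal(res2$statistic, 1)

  extreme <- c(rep(0.05, 600), rep(0.95, 600))
  res3 <- bimodality_check(extreme)
  expect_equal(res3$statistic, 0)
  expect_true(res3$pass)

  expect_error(bimodality_check(runif(100)), "1000")
})

test_that("PCA check flags a shifted sample and sees no artificial batch effect", {
  cohort <- simulate_methylation_cohort(
    sim_config(seed = 31, n_probes = 2000, n_informative = 1,
               effect_delta = 0))
  b <- cohort$betas
  # at n = 80 a 3-SD cut admits occasional chance flags; a gross-outlier
  # cut of 4 robust SDs flags nothing in a homogeneous cohort
  res <- pca_outlier_check(b, z_thresh = 4)
  expect_length(res$flagged, 0L)

  # spike one sample: 30% of probes shifted up by 0.4
  spiked <- b
  idx <- seq_len(0.3 * nrow(b))
  spiked[idx, "S005"] <- pmin(spiked[idx, "S005"] + 0.4, 1)
  res2 <- pca_outlier_check(spiked)
  expect_true("S005" %in% res2$flagged)

  # two batches drawn from the same distribution separate by ~0
  batch <- rep(c("A", "B"), length.out = ncol(b))
  res3 <- pca_outlier_check(b, batch = batch)
  expect_true(all(res3$batch_separation < 1))

  expect_error(pca_outlier_check(b[, 1:2]), ">= 3")
})
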