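# Probe-wise AUC, three-step feature selection, base learners, stacking,
# fold metrics and cross-validation mechanics.

test_that("probe-wise AUC matches pair enumeration, with midrank ties", {
  # 4 pairs, 3 concordant
  expect_equal(probe_wise_auc(c(0.8, 0.6, 0.7, 0.5),
                              c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  # perfect separation
  expect_equal(probe_wise_auc(c(9, 8, 7, 2, 1), rep(c(TRUE, FALSE), c(3, 2))),
               1.0)
  expect_error(probe_wise_auc(1:4, rep(TRUE, 4)), "both classes")

  # property: midrank AUC equals the brute-force pair count, ties included
  set.seed(42)
  for (i in 1:25) {
    x <- sample(seq(0, 1, by = 0.1), 14, replace = TRUE)  # forces ties
    y <- sample(c(TRUE, FALSE), 14, replace = TRUE, prob = c(.5, .5))
    if (!any(y) || all(y)) next
    expect_equal(probe_wise_auc(x, y), brute_force_auc(x, y))
  }

  # permuted labels on a large sample sit near 0.5
  set.seed(7)
  x <- runif(400)
  y <- sample(rep(c(TRUE, FALSE), 200))
  expect_lt(abs(probe_wise_auc(x, y) - 0.5), 0.08)
})

test_that("probe-wise AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  x <- rnorm(40)
  y <- rep(c(TRUE, FALSE), 20)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, x,
    direction = "<", quiet = TRUE))))
  expect_equal(probe_wise_auc(x, y), ref)
})

test_that("mean-difference filter is strict and duplicates are pruned", {
  # dyadic values so the group-mean differences are exact in floating point:
  # probe A sits exactly at the threshold (excluded by strictness), B above
  # it, and C/D are duplicates of which exactly one survives pruning
  pos <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  b <- rbind(
    A = c(rep(0.5625, 3), rep(0.5, 3)),       # delta = 0.0625 exactly
    B = c(rep(0.6250, 3), rep(0.5, 3)),       # delta = 0.125
    C = c(0.80, 0.82, 0.84, 0.40, 0.42, 0.44),
    D = c(0.80, 0.82, 0.84, 0.40, 0.42, 0.44)
  )
  colnames(b) <- sprintf("s%d", 1:6)
  fs <- select_features(b, pos, delta_min = 0.0625)
  expect_false("A" %in% fs$probes)
  expect_true("B" %in% fs$probes)
  expect_equal(sum(c("C", "D") %in% fs$probes), 1L)
  expect_equal(fs$pruning_log$probe, setdiff(c("C", "D"), fs$probes))
  expect_equal(fs$pruning_log$r2, 1)

  # no survivor: empty result with a warning, not an error
  flat <- matrix(0.5, 4, 6, dimnames = list(sprintf("p%d", 1:4),
                                            sprintf("s%d", 1:6)))
  expect_warning(fs0 <- select_features(flat, pos), "no probe")
  expect_length(fs0$probes, 0L)
})

test_that("selection on a planted cohort retains signal probes", {
  cohort <- simulate_methylation_cohort(
    sim_config(seed = 41, n_probes = 2000, n_informative = 100))
  fs <- select_features(cohort$betas, cohort$labels)
  planted_blocks <- cohort$truth$informative_blocks
  block_of <- cohort$truth$block_of
  in_signal <- block_of[fs$probes] %in% planted_blocks
  expect_gte(mean(in_signal), 0.9)
  # the pruning log names real block-mates
  expect_gt(nrow(fs$pruning_log), 0)
})

test_that("base learners separate a separable toy set and are seed-stable", {
  toy <- separable_toy(6)
  bm <- train_base_models(toy$x, toy$y, seed = 3)
  sc <- predict(bm, toy$x)
  expect_equal(dim(sc), c(12L, 6L))
  expect_true(all(sc >= 0 & sc <= 1))
  for (nm in colnames(sc)) {
    expect_equal(probe_wise_auc(sc[, nm], toy$y), 1.0, info = nm)
  }

  # deterministic given the seed (including the stochastic forest)
  bm2 <- train_base_models(toy$x, toy$y, seed = 3)
  expect_equal(predict(bm2, toy$x), sc)

  expect_error(train_base_models(toy$x[1:6, ], toy$y[1:6]), "5 training")
  flat <- matrix(1, 12, 3)
  expect_error(train_base_models(flat, toy$y), "degenerate")
})

test_that("shuffled labels give chance-level held-out scores", {
  set.seed(13)
  x <- matrix(rnorm(60 * 20), 60, 20,
              dimnames = list(NULL, sprintf("f%d", 1:20)))
  y <- rep(c(TRUE, FALSE), 30)
  bm <- train_base_models(x[1:40, ], y[1:40], seed = 5)
  sc <- predict(bm, x[41:60, ])
  aucs <- apply(sc, 2, function(s) {
    if (sd(s) == 0) 0.5 else probe_wise_auc(s, y[41:60])
  })
  expect_true(all(aucs > 0.15 & aucs < 0.85))
})

test_that("stacking puts its weight on a perfect learner", {
  set.seed(17)
  y <- rep(c(TRUE, FALSE), each = 20)
  z <- cbind(
    perfect = ifelse(y, 0.9, 0.1),
    matrix(runif(40 * 5), 40, 5,
           dimnames = list(NULL, sprintf("noise%d", 1:5)))
  )
  w <- fit_ensemble(z, y, seed = 1)
  expect_gte(w$weights[["perfect"]], 0.9)
  expect_true(all(w$weights >= 0))
  expect_equal(sum(w$weights), 1)
})

test_that("identical learners collapse onto the first column", {
  y <- rep(c(TRUE, FALSE), each = 10)
  p <- ifelse(y, 0.8, 0.2) + rep(c(0.01, -0.01), 10)
  z <- matrix(p, 20, 6, dimnames = list(NULL, sprintf("m%d", 1:6)))
  w <- fit_ensemble(z, y, seed = 2)
  expect_equal(unname(w$weights["m1"]), 1)
  expect_true(all(w$weights[-1] == 0))
})

test_that("an all-zero stacking solution falls back to the best learner", {
  y <- rep(c(TRUE, FALSE), each = 10)
  z <- cbind(
    anti = ifelse(y, 0.1, 0.9),        # negative association: clipped to 0
    flat = rep(0.5, 20)
  )
  w <- fit_ensemble(z, y, seed = 3)
  expect_true(w$fallback)
  expect_equal(unname(w$weights[["flat"]]), 1)
})

test_that("fold metrics reproduce the derived fold-1 confusion matrix", {
  cv <- confusion_vectors(tp = 6, fn = 3, fp = 2, tn = 5)
  m <- compute_metrics(cv$truth, cv$scores)
  expect_equal(m$accuracy, 11 / 16)
  expect_equal(m$sensitivity, 6 / 9)
  expect_equal(m$specificity, 5 / 7)
  expect_equal(m$ppv, 6 / 8)
  expect_equal(m$npv, 5 / 8)
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(6, 3, 2, 5))
})

test_that("metric edge cases: perfect, constant, and empty prediction cells", {
  perfect <- compute_metrics(rep(c(TRUE, FALSE), 5),
                             rep(c(1, 0), 5))
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv",
               "auc")) {
    expect_equal(perfect[[nm]], 1.0, info = nm)
  }

  const <- compute_metrics(rep(c(TRUE, FALSE), 5), rep(0.4, 10))
  expect_equal(const$auc, 0.5)     # midrank convention
  expect_true(is.na(const$ppv))    # nothing predicted positive
  expect_equal(const$npv, 0.5)

  expect_error(compute_metrics(rep(TRUE, 4), runif(4)), "both classes")
})

test_that("fold averages of the packaged metric table match its printed means", {
  rep2 <- load_table2_fixture()
  printed <- attr(rep2, "printed_average")
  expect_true(all(abs(rep2$average - printed) <= 0.005))
})

test_that("cross-validation is stratified and honours the fold count", {
  cohort <- simulate_methylation_cohort(
    sim_config(seed = 43, n_probes = 800, n_informative = 60,
               n_pos = 20, n_neg = 16))
  cv <- cross_validate(cohort, k = 2, seed = 1)
  expect_equal(nrow(cv$folds), 2L)
  # stratification: each fold holds about half of each class
  pos <- cohort$labels == "positive"
  for (f in 1:2) {
    expect_lte(abs(sum(pos[cv$fold_assignment == f]) - 10), 1)
  }
  # strong planted signal is recovered out of fold
  expect_gte(cv$average[["auc"]], 0.9)
  # determinism of the whole procedure
  cv2 <- cross_validate(cohort, k = 2, seed = 1)
  expect_equal(cv$folds, cv2$folds)
  expect_error(cross_validate(cohort, k = 1, seed = 1), "at least 2")
})

test_that("ensemble tracks its best base learner on internal AUC", {
  cohort <- simulate_methylation_cohort(
    sim_config(seed = 44, n_probes = 800, n_informative = 60,
               n_pos = 18, n_neg = 18))
  fit <- brcaness_fit(cohort, seed = 2)
  ens_auc <- probe_wise_auc(
    drop(fit$oos_predictions %*% fit$ensemble$weights), fit$labels)
  expect_gte(ens_auc, max(fit$ensemble$internal_auc) - 0.05)
})
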