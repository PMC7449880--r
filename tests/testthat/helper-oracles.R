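# Independent oracles and small fixture builders used across the suite.

# Brute-force AUC: count concordant score pairs across the two classes,
# ties worth one half. Independent of the midrank implementation.
brute_force_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  conc <- 0
  for (p in pos) for (n in neg) {
    conc <- conc + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  conc / (length(pos) * length(neg))
}

# Score/truth vectors realizing a given confusion matrix at threshold 0.5.
confusion_vectors <- function(tp, fn, fp, tn) {
  list(
    truth = rep(c(TRUE, FALSE), c(tp + fn, fp + tn)),
    scores = c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
  )
}

# Tiny deterministic beta matrix: probes x samples from explicit values.
toy_beta_matrix <- function(values, probe_ids, sample_ids) {
  matrix(values, nrow = length(probe_ids), byrow = TRUE,
         dimnames = list(probe_ids, sample_ids))
}

# Deterministic linearly separable toy set (two features).
separable_toy <- function(n_per_class = 6) {
  x <- rbind(
    cbind(seq(1, 2, length.out = n_per_class),
          seq(1.5, 2.5, length.out = n_per_class)),
    cbind(seq(-2, -1, length.out = n_per_class),
          seq(-2.5, -1.5, length.out = n_per_class))
  )
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(TRUE, FALSE), each = n_per_class))
}
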