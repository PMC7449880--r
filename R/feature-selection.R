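# Three-step univariate feature selection for the methylation classifier:
# (1) group-mean beta difference filter, (2) AUC ranking with a cap, (3)
# greedy within-class correlation pruning.

#' Probe-wise rank AUC
#'
#' Mann-Whitney (midrank) AUC of each probe's beta value as a score for the
#' positive class. Values below 0.5 indicate hypomethylated markers (the
#' probe ranks negatives higher).
#'
#' @param betas numeric vector (one probe) or probes x samples matrix.
#' @param labels sample labels; logical or factor with level `"positive"`;
#'   both classes must be present.
#' @return a single AUC, or a named vector per probe for matrix input.
#' @examples
#' probe_wise_auc(c(0.8, 0.6, 0.7, 0.5), c(TRUE, TRUE, FALSE, FALSE))
#' @export
probe_wise_auc <- function(betas, labels) {
  pos <- .as_positive(labels)
  if (is.matrix(betas)) {
    stopifnot(ncol(betas) == length(pos))
    apply(betas, 1, rank_auc, positive = pos)
  } else {
    stopifnot(length(betas) == length(pos))
    rank_auc(betas, pos)
  }
}

#' Select discriminative probes on a training cohort
#'
#' Step 1 retains probes whose absolute group-mean beta difference strictly
#' exceeds `delta_min`. Step 2 ranks the survivors by AUC and keeps the top
#' `top_n`; with `fold_directions = TRUE` (default) the ranking statistic is
#' `max(AUC, 1 - AUC)` so hypo- and hypermethylated markers compete
#' symmetrically, otherwise the raw AUC is used. Step 3 walks the ranked
#' list and drops any probe whose squared Pearson correlation with an
#' already-kept probe exceeds `r2_max`, computed separately within cases
#' and controls (`prune_scope = "either"` prunes when either class exceeds
#' the cut; `"both"` requires both).
#'
#' @param betas probes x samples beta matrix (training samples only).
#' @param labels training labels (see [probe_wise_auc()]).
#' @param delta_min minimum absolute group-mean difference (strict).
#' @param top_n AUC-ranking cap.
#' @param r2_max within-class R-squared above which (strictly) a probe is
#'   pruned against an already-kept probe.
#' @param fold_directions rank by `max(AUC, 1 - AUC)` instead of raw AUC.
#' @param prune_scope `"either"` (default) or `"both"`.
#' @return object of class `feature_selection`: list with `probes`
#'   (retained ids, ranking order), `delta` and `auc` (named, all step-1
#'   survivors), `pruning_log` (data.frame: probe, partner, class, r2) and
#'   the parameters used. Zero step-1 survivors yield an empty result with
#'   a warning.
#' @examples
#' cohort <- simulate_methylation_cohort(sim_config(seed = 1,
#'   n_probes = 300, n_informative = 20, n_pos = 12, n_neg = 12))
#' fs <- select_features(cohort$betas, cohort$labels)
#' length(fs$probes)
#' @export
select_features <- function(betas, labels, delta_min = 0.05, top_n = 1000,
                            r2_max = 0.8, fold_directions = TRUE,
                            prune_scope = c("either", "both")) {
  prune_scope <- match.arg(prune_scope)
  pos <- .as_positive(labels)
  stopifnot(is.matrix(betas), ncol(betas) == length(pos))
  if (!any(pos) || all(pos)) {
    stop_brcadx("feature selection requires both classes")
  }

  delta <- rowMeans(betas[, pos, drop = FALSE]) -
    rowMeans(betas[, !pos, drop = FALSE])
  keep1 <- which(abs(delta) > delta_min)  # strict
  empty <- structure(list(
    probes = character(), delta = numeric(), auc = numeric(),
    pruning_log = data.frame(probe = character(), partner = character(),
                             class = character(), r2 = numeric()),
    params = list(delta_min = delta_min, top_n = top_n, r2_max = r2_max,
                  fold_directions = fold_directions,
                  prune_scope = prune_scope)
  ), class = "feature_selection")
  if (!length(keep1)) {
    warning("no probe passed the mean-difference filter", call. = FALSE)
    return(empty)
  }

  auc <- probe_wise_auc(betas[keep1, , drop = FALSE], pos)
  score <- if (fold_directions) pmax(auc, 1 - auc) else auc
  ord <- order(score, decreasing = TRUE)
  ranked <- keep1[ord][seq_len(min(top_n, length(ord)))]

  x_pos <- t(betas[ranked, pos, drop = FALSE])
  x_neg <- t(betas[ranked, !pos, drop = FALSE])
  kept <- integer()
  log_rows <- list()
  for (j in seq_along(ranked)) {
    if (!length(kept)) { kept <- j; next }
    r2p <- suppressWarnings(
      stats::cor(x_pos[, j], x_pos[, kept, drop = FALSE])^2)
    r2n <- suppressWarnings(
      stats::cor(x_neg[, j], x_neg[, kept, drop = FALSE])^2)
    r2p[!is.finite(r2p)] <- 0
    r2n[!is.finite(r2n)] <- 0
    hit <- if (prune_scope == "either") {
      pmax(r2p, r2n) > r2_max  # strict: R^2 == r2_max is kept
    } else {
      pmin(r2p, r2n) > r2_max
    }
    if (any(hit)) {
      w <- which.max(pmax(r2p, r2n) * hit)
      cls <- if (r2p[w] >= r2n[w]) "positive" else "negative"
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        probe = rownames(betas)[ranked[j]],
        partner = rownames(betas)[ranked[kept[w]]],
        class = cls, r2 = max(r2p[w], r2n[w]),
        stringsAsFactors = FALSE
      )
    } else {
      kept <- c(kept, j)
    }
  }

  out <- empty
  out$probes <- rownames(betas)[ranked[kept]]
  out$delta <- stats::setNames(delta[keep1], rownames(betas)[keep1])
  out$auc <- auc
  out$pruning_log <- if (length(log_rows)) {
    do.call(rbind, c(log_rows, list(make.row.names = FALSE)))
  } else out$pruning_log
  out
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf(
    "<feature_selection> %d probes retained (%d passed delta filter, %d pruned)\n",
    length(x$probes), length(x$delta), nrow(x$pruning_log)
  ))
  invisible(x)
}
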