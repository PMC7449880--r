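# Fold-level classification metrics and the cross-validation report
# container (five fold rows plus their arithmetic means).

.metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                   "auc")

.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) return(labels == "positive")
  if (is.character(labels)) return(labels == "positive")
  if (is.numeric(labels)) return(labels > 0)
  stop_brcadx("cannot interpret labels")
}

#' Confusion-matrix metrics and AUC for one fold
#'
#' Scores at or above `threshold` predict the positive class. Accuracy,
#' sensitivity, specificity, PPV and NPV come from the confusion matrix;
#' AUC is the rank-based (Mann-Whitney, midrank ties) statistic on the
#' continuous scores. PPV is reported as `NA` ("missing") when no positive
#' predictions exist, NPV likewise; they are never NaN-propagated.
#'
#' @param truth true labels: logical, or factor/character with level
#'   `"positive"`; both classes must be present.
#' @param scores numeric scores in `[0, 1]` (higher = more positive).
#' @param threshold classification threshold on the score.
#' @return object of class `fold_metrics`: named list with the six metrics
#'   and the confusion counts `tp`, `fn`, `fp`, `tn`.
#' @examples
#' m <- compute_metrics(rep(c(TRUE, FALSE), c(9, 7)),
#'   c(rep(1, 6), rep(0, 3), rep(1, 2), rep(0, 5)))
#' m$accuracy
#' @export
compute_metrics <- function(truth, scores, threshold = 0.5) {
  truth <- .as_positive(truth)
  stopifnot(length(truth) == length(scores))
  if (!any(truth) || all(truth)) {
    stop_brcadx("metrics require both classes in 'truth'")
  }
  pred <- scores >= threshold
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  out <- list(
    accuracy = (tp + tn) / length(truth),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    npv = if (tn + fn == 0) NA_real_ else tn / (tn + fn),
    auc = rank_auc(scores, truth),
    tp = tp, fn = fn, fp = fp, tn = tn
  )
  structure(out, class = "fold_metrics")
}

#' @export
print.fold_metrics <- function(x, digits = 3, ...) {
  cat(sprintf(
    "accuracy %.*f | sensitivity %.*f | specificity %.*f | PPV %s | NPV %s | AUC %.*f\n",
    digits, x$accuracy, digits, x$sensitivity, digits, x$specificity,
    if (is.na(x$ppv)) "NA" else formatC(x$ppv, digits = digits, format = "f"),
    if (is.na(x$npv)) "NA" else formatC(x$npv, digits = digits, format = "f"),
    digits, x$auc
  ))
  invisible(x)
}

#' Cross-validation report container
#'
#' Holds per-fold metric rows and their arithmetic means (computed before
#' any rounding; folds with a missing metric are skipped for that metric's
#' mean, with a warning at construction when that happens).
#'
#' @param folds data.frame with columns `fold` and the six metrics.
#' @param ... further fields stored alongside (fold feature lists, ensemble
#'   weights, out-of-fold scores, seed).
#' @return object of class `cv_report`: list with `folds`, `average` and
#'   any extra fields.
#' @export
new_cv_report <- function(folds, ...) {
  stopifnot(is.data.frame(folds), all(.metric_names %in% names(folds)))
  mat <- as.matrix(folds[.metric_names])
  if (anyNA(mat)) {
    warning("fold(s) with missing metrics; averages skip them",
            call. = FALSE)
  }
  avg <- colMeans(mat, na.rm = TRUE)
  structure(list(folds = folds, average = avg, ...), class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 2, ...) {
  k <- nrow(x$folds)
  cat(sprintf("Cross-validation report (%d folds)\n", k))
  tab <- rbind(t(as.matrix(x$folds[.metric_names])),
               deparse.level = 0)
  tab <- cbind(tab, Average = x$average)
  colnames(tab)[seq_len(k)] <- sprintf("Fold %d", x$folds$fold)
  rownames(tab) <- c("Overall accuracy", "Sensitivity", "Specificity",
                     "PPV", "NPV", "AUC")
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  cat("Averaged cross-validated metrics:\n")
  print(round(object$average, 3))
  invisible(object$average)
}

#' @export
as.data.frame.cv_report <- function(x, ...) x$folds
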