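# The BRCAness methylation classifier: feature selection + six base
# learners + non-negative lasso stacking, wrapped as a fitted-model object,
# and leakage-free stratified k-fold cross-validation around it.

.cohort_parts <- function(betas, labels) {
  if (inherits(betas, "meth_cohort")) {
    labels <- labels %||% betas$labels
    betas <- betas$betas
  }
  stopifnot(is.matrix(betas), !is.null(labels),
            ncol(betas) == length(labels))
  list(betas = betas, pos = .as_positive(labels))
}

# Stratified fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(pos, k, seed) {
  stopifnot(k >= 2L)
  fold <- integer(length(pos))
  with_rng(seed, {
    for (cls in unique(pos)) {
      idx <- sample(which(pos == cls))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  if (min(table(pos)) < k) {
    warning("a class has fewer samples than folds; some folds may miss it",
            call. = FALSE)
  }
  fold
}

#' Fit the BRCAness methylation classifier
#'
#' Runs the full training procedure on a labelled cohort: three-step
#' feature selection ([select_features()]), six base learners
#' ([train_base_models()]), and a non-negative lasso stacking ensemble
#' fitted on out-of-sample base predictions from an internal stratified
#' cross-validation of the training data (standard stacked-generalization
#' construction), then refits the base learners on the whole training set.
#'
#' @param betas probes x samples training beta matrix, or a `meth_cohort`.
#' @param labels training labels (ignored when a cohort is passed).
#' @param seed RNG seed governing internal folds and stochastic learners.
#' @param internal_folds folds of the internal stacking cross-validation.
#' @param select named list of arguments for [select_features()].
#' @param hyper named list of base-learner hyperparameters.
#' @return object of class `brcaness_fit` with methods [predict.brcaness_fit()],
#'   `print`, `summary` and `coef` (the ensemble weights).
#' @examples
#' \donttest{
#' cohort <- simulate_methylation_cohort(sim_config(seed = 1,
#'   n_probes = 1000, n_informative = 50, n_pos = 20, n_neg = 20))
#' fit <- brcaness_fit(cohort, seed = 1)
#' head(predict(fit, cohort$betas))
#' }
#' @export
brcaness_fit <- function(betas, labels = NULL, seed = 1L,
                         internal_folds = 5L, select = list(),
                         hyper = list()) {
  parts <- .cohort_parts(betas, labels)
  x <- parts$betas
  pos <- parts$pos

  fs <- do.call(select_features,
                c(list(betas = x, labels = pos), select))
  if (!length(fs$probes)) {
    # nothing discriminative on this training set: degrade to an honest
    # uninformative predictor (constant 0.5) instead of failing the fold
    warning("no probes selected; fitting a constant 0.5 predictor",
            call. = FALSE)
    return(structure(list(
      features = fs, base_models = NULL, ensemble = NULL,
      oos_predictions = NULL, labels = pos, seed = seed,
      internal_folds = 0L, constant = 0.5
    ), class = "brcaness_fit"))
  }
  feat <- t(x[fs$probes, , drop = FALSE])

  # out-of-sample base predictions within the training partition
  k <- min(internal_folds, min(table(pos)))
  fold <- stratified_folds(pos, k, derive_seed(seed, 11))
  oos <- matrix(NA_real_, nrow(feat), 6)
  for (f in seq_len(k)) {
    tr <- fold != f
    bm <- train_base_models(feat[tr, , drop = FALSE], pos[tr],
                            seed = derive_seed(seed, 20 + f),
                            hyper = hyper)
    oos[!tr, ] <- predict(bm, feat[!tr, , drop = FALSE])
  }
  colnames(oos) <- names(.learner_specs(hyper))
  ens <- fit_ensemble(oos, pos, seed = derive_seed(seed, 31))
  base <- train_base_models(feat, pos, seed = derive_seed(seed, 41),
                            hyper = hyper)

  structure(list(
    features = fs,
    base_models = base,
    ensemble = ens,
    oos_predictions = oos,
    labels = pos,
    seed = seed,
    internal_folds = k
  ), class = "brcaness_fit")
}

#' Predict BRCAness scores for new samples
#'
#' @param object a fitted [brcaness_fit()] model.
#' @param newdata probes x samples beta matrix containing at least the
#'   model's selected probes, or a samples x features matrix whose columns
#'   already match the selected probes.
#' @param ... unused.
#' @return named numeric vector of ensemble scores in `[0, 1]` (probability
#'   of the BRCA1/2-deficient class).
#' @export
predict.brcaness_fit <- function(object, newdata, ...) {
  if (!is.null(object$constant)) {
    n <- if (is.matrix(newdata)) ncol(newdata) else length(newdata)
    return(stats::setNames(rep(object$constant, n),
                           if (is.matrix(newdata)) colnames(newdata)))
  }
  probes <- object$features$probes
  if (is.matrix(newdata) && all(probes %in% rownames(newdata))) {
    feat <- t(newdata[probes, , drop = FALSE])
  } else if (is.matrix(newdata) &&
             identical(colnames(newdata), probes)) {
    feat <- newdata
  } else {
    stop_brcadx("newdata must contain the model's selected probes")
  }
  scores <- predict(object$base_models, feat)
  drop(.clip01(scores %*% object$ensemble$weights[colnames(scores)]))
}

#' @export
print.brcaness_fit <- function(x, ...) {
  cat(sprintf(
    "<brcaness_fit> %d features | %d training samples (%d positive)\n",
    length(x$features$probes), length(x$labels), sum(x$labels)
  ))
  if (is.null(x$ensemble)) {
    cat(sprintf("degenerate fit: constant score %.2f\n", x$constant))
  } else {
    cat("ensemble weights:\n")
    print(round(x$ensemble$weights, 3))
  }
  invisible(x)
}

#' @export
summary.brcaness_fit <- function(object, ...) {
  cat(sprintf("BRCAness classifier: %d selected probes, %d pruned\n",
              length(object$features$probes),
              nrow(object$features$pruning_log)))
  if (is.null(object$ensemble)) {
    cat(sprintf("degenerate fit: constant score %.2f\n", object$constant))
    return(invisible(object))
  }
  cat(sprintf("internal stacking folds: %d\n", object$internal_folds))
  cat("internal out-of-sample AUC per learner:\n")
  print(round(object$ensemble$internal_auc, 3))
  cat("ensemble weights",
      if (object$ensemble$fallback) "(fallback)" else "", ":\n")
  print(round(object$ensemble$weights, 3))
  invisible(object)
}

#' @export
coef.brcaness_fit <- function(object, ...) {
  if (is.null(object$ensemble)) return(NULL)
  object$ensemble$weights
}

#' Cross-validate the BRCAness classifier
#'
#' Stratified random k-fold cross-validation. In every fold, feature
#' selection and all model fitting (base learners and stacking) see only
#' the training folds; the held-out fold contributes nothing to selection
#' statistics or fits. Per-fold metrics and their arithmetic means are
#' reported; a fold missing a class is reported with missing metrics and
#' skipped in the averaging with a warning.
#'
#' @param betas probes x samples beta matrix, or a `meth_cohort`.
#' @param labels labels (ignored for a cohort).
#' @param k number of folds.
#' @param seed RNG seed (fold split, learners).
#' @param threshold ensemble-score classification threshold.
#' @inheritParams brcaness_fit
#' @return a [new_cv_report()] with extra fields `fold_features` (selected
#'   probes per fold), `fold_weights` (ensemble weights per fold),
#'   `oof_scores` (out-of-fold ensemble score per sample) and `seed`.
#' @examples
#' \donttest{
#' cohort <- simulate_methylation_cohort(sim_config(seed = 1,
#'   n_probes = 1000, n_informative = 50, n_pos = 20, n_neg = 20))
#' cv <- cross_validate(cohort, seed = 1)
#' cv$average
#' }
#' @export
cross_validate <- function(betas, labels = NULL, k = 5L, seed = 1L,
                           threshold = 0.5, internal_folds = 5L,
                           select = list(), hyper = list()) {
  parts <- .cohort_parts(betas, labels)
  x <- parts$betas
  pos <- parts$pos
  k <- assert_count(k, "k")
  if (k < 2L) stop_brcadx("'k' must be at least 2")

  fold <- stratified_folds(pos, k, derive_seed(seed, 1))
  oof <- rep(NA_real_, length(pos))
  names(oof) <- colnames(x)
  fold_features <- vector("list", k)
  fold_weights <- vector("list", k)
  rows <- vector("list", k)

  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    fit <- brcaness_fit(x[, tr, drop = FALSE], pos[tr],
                        seed = derive_seed(seed, 100 + f),
                        internal_folds = internal_folds,
                        select = select, hyper = hyper)
    fold_features[[f]] <- fit$features$probes
    fold_weights[[f]] <- fit$ensemble$weights
    sc <- predict(fit, x[, te, drop = FALSE])
    oof[te] <- sc
    rows[[f]] <- if (length(unique(pos[te])) < 2L) {
      data.frame(fold = f, accuracy = NA_real_, sensitivity = NA_real_,
                 specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
                 auc = NA_real_)
    } else {
      m <- compute_metrics(pos[te], sc, threshold = threshold)
      data.frame(fold = f, accuracy = m$accuracy,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 ppv = m$ppv, npv = m$npv, auc = m$auc)
    }
  }
  folds <- do.call(rbind, rows)
  new_cv_report(folds,
                fold_features = fold_features,
                fold_weights = fold_weights,
                oof_scores = oof,
                fold_assignment = fold,
                seed = seed)
}
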