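# The six base learners and the non-negative lasso stacking step.
# Each learner exposes a probability-like score in [0, 1] for the positive
# class; hyperparameters are fixed defaults, tunable only through the
# `hyper` list (no outer tuning).

.default_hyper <- list(
  enet_alpha = 0.5,        # elastic-net mixing
  svm_cost = 1,            # SVM cost (both kernels)
  rbf_gamma = NULL,        # NULL = 1 / n_features
  lda_components = 10,     # principal components fed to the discriminant
  rf_ntree = 300,          # forest size
  ridge_lambda = 0.05      # Gaussian-prior scale of the MAP logistic model
)

.clip01 <- function(p) pmin(pmax(p, 0), 1)

.learner_specs <- function(hyper) {
  h <- utils::modifyList(.default_hyper, hyper)
  list(
    elastic_net = list(
      fit = function(x, y) {
        # small internal partitions trigger glmnet sample-size notices
        cv <- suppressWarnings(
          glmnet::cv.glmnet(x, y, family = "binomial",
                            alpha = h$enet_alpha,
                            nfolds = min(5L, floor(length(y) / 2))))
        list(fit = cv$glmnet.fit, lambda = cv$lambda.min)
      },
      predict = function(m, x) {
        .clip01(as.numeric(stats::predict(m$fit, x, s = m$lambda,
                                          type = "response")))
      }
    ),
    svm_linear = list(
      fit = function(x, y) {
        e1071::svm(x, factor(y, levels = c(FALSE, TRUE)),
                   kernel = "linear", cost = h$svm_cost,
                   probability = TRUE, scale = FALSE)
      },
      predict = function(m, x) {
        p <- attr(stats::predict(m, x, probability = TRUE), "probabilities")
        .clip01(p[, "TRUE"])
      }
    ),
    svm_rbf = list(
      fit = function(x, y) {
        e1071::svm(x, factor(y, levels = c(FALSE, TRUE)),
                   kernel = "radial", cost = h$svm_cost,
                   gamma = h$rbf_gamma %||% (1 / ncol(x)),
                   probability = TRUE, scale = FALSE)
      },
      predict = function(m, x) {
        p <- attr(stats::predict(m, x, probability = TRUE), "probabilities")
        .clip01(p[, "TRUE"])
      }
    ),
    lda = list(
      fit = function(x, y) {
        # discriminant on top PCs: LDA itself is singular when p >= n
        k <- max(1L, min(h$lda_components, nrow(x) - 2L, ncol(x)))
        pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = k)
        keep <- which(pc$sdev[seq_len(k)] > 1e-8)
        if (!length(keep)) return(list(constant = mean(y)))
        list(pc = pc, keep = keep,
             lda = MASS::lda(pc$x[, keep, drop = FALSE],
                             grouping = factor(y)))
      },
      predict = function(m, x) {
        if (!is.null(m$constant)) return(rep(m$constant, nrow(x)))
        sc <- stats::predict(m$pc, x)[, m$keep, drop = FALSE]
        .clip01(stats::predict(m$lda, sc)$posterior[, "TRUE"])
      }
    ),
    random_forest = list(
      fit = function(x, y) {
        randomForest::randomForest(x, factor(y, levels = c(FALSE, TRUE)),
                                   ntree = h$rf_ntree)
      },
      predict = function(m, x) {
        .clip01(stats::predict(m, x, type = "prob")[, "TRUE"])
      }
    ),
    bayes_glm = list(
      fit = function(x, y) {
        # MAP logistic regression under a Gaussian coefficient prior
        glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = h$ridge_lambda)
      },
      predict = function(m, x) {
        .clip01(as.numeric(stats::predict(m, x, type = "response")))
      }
    )
  )
}

#' Train the six base learners
#'
#' Fits the base classifiers on a training feature matrix: elastic-net
#' logistic regression, linear- and RBF-kernel SVMs, a linear discriminant
#' (on top principal components), a random forest, and a Gaussian-prior MAP
#' (ridge) logistic model. Features are standardized internally with
#' training-set statistics only; constant features get unit scale. Every
#' learner's prediction is a probability-like score in `[0, 1]` for the
#' positive class.
#'
#' @param x samples x features numeric matrix.
#' @param labels training labels (both classes, at least 5 samples each).
#' @param seed RNG seed for the stochastic learners.
#' @param hyper named list overriding entries of the default hyperparameter
#'   set (`enet_alpha`, `svm_cost`, `rbf_gamma`, `lda_components`,
#'   `rf_ntree`, `ridge_lambda`).
#' @return object of class `base_models` with a `predict` method returning
#'   a samples x 6 score matrix.
#' @export
train_base_models <- function(x, labels, seed = 1L, hyper = list()) {
  y <- .as_positive(labels)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (sum(y) < 5L || sum(!y) < 5L) {
    stop_brcadx("need at least 5 training samples per class")
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (all(scl == 0)) {
    stop_brcadx("degenerate feature matrix: all features constant")
  }
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  if (ncol(xs) == 1L) {
    # several learners need >= 2 columns; a zero column changes no fit
    xs <- cbind(xs, `.pad` = 0)
  }

  specs <- .learner_specs(hyper)
  models <- with_rng(seed, {
    lapply(specs, function(sp) sp$fit(xs, y))
  })
  structure(list(
    models = models, specs = specs, center = ctr, scale = scl,
    learners = names(specs), seed = seed
  ), class = "base_models")
}

#' @export
predict.base_models <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == length(object$center))
  xs <- scale(newdata, center = object$center, scale = object$scale)
  if (ncol(xs) == 1L) xs <- cbind(xs, `.pad` = 0)
  out <- vapply(object$learners, function(nm) {
    object$specs[[nm]]$predict(object$models[[nm]], xs)
  }, numeric(nrow(newdata)))
  out <- matrix(out, nrow = nrow(newdata),
                dimnames = list(rownames(newdata), object$learners))
  out
}

#' @export
print.base_models <- function(x, ...) {
  cat("<base_models>", paste(x$learners, collapse = ", "), "\n")
  invisible(x)
}

#' Combine base-learner predictions by non-negative lasso stacking
#'
#' Solves an L1-penalized least-squares regression of the labels on the
#' out-of-sample base predictions with non-negative coefficients, picks the
#' penalty by internal cross-validation, and renormalizes the surviving
#' coefficients to sum to 1. If the selected penalty zeroes every
#' coefficient, the single learner with the best internal AUC gets weight 1
#' (fallback, flagged). Learners with identical prediction columns are
#' collapsed onto the first of each identical group, which makes the
#' tie-break deterministic.
#'
#' @param predictions samples x learners matrix of out-of-sample base
#'   predictions (from internal validation splits of the training
#'   partition).
#' @param labels training labels aligned to the rows.
#' @param seed RNG seed for the internal penalty cross-validation.
#' @return object of class `ensemble_weights`: list with `weights` (named,
#'   non-negative, summing to 1), `fallback` (logical), and `internal_auc`
#'   (per-learner AUC of the out-of-sample predictions).
#' @export
fit_ensemble <- function(predictions, labels, seed = 1L) {
  y <- as.numeric(.as_positive(labels))
  stopifnot(is.matrix(predictions), nrow(predictions) == length(y))
  learners <- colnames(predictions) %||%
    sprintf("learner%d", seq_len(ncol(predictions)))
  colnames(predictions) <- learners

  internal_auc <- apply(predictions, 2, function(p) {
    if (stats::sd(p) == 0) 0.5 else rank_auc(p, y > 0.5)
  })

  # collapse exactly identical columns onto their first occurrence
  key <- apply(round(predictions, 12), 2, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  z <- predictions[, first, drop = FALSE]

  weights <- stats::setNames(rep(0, length(learners)), learners)
  fallback <- FALSE
  if (ncol(z) == 1L || stats::sd(y) == 0) {
    weights[learners[first][1]] <- 1
  } else {
    fit <- with_rng(seed, {
      suppressWarnings(
        glmnet::cv.glmnet(z, y, alpha = 1, lower.limits = 0,
                          nfolds = min(5L, max(3L, floor(length(y) / 4)))))
    })
    co <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1]
    if (all(co <= 0)) {
      fallback <- TRUE
      best <- which.max(internal_auc)  # first max wins ties
      weights[best] <- 1
    } else {
      w <- pmax(co, 0)
      w <- w / sum(w)
      weights[learners[first]] <- w
    }
  }
  structure(list(weights = weights, fallback = fallback,
                 internal_auc = internal_auc, column_map = map),
            class = "ensemble_weights")
}

#' @export
print.ensemble_weights <- function(x, digits = 3, ...) {
  cat("<ensemble_weights>",
      if (x$fallback) "(fallback to best single learner)" else "", "\n")
  print(round(x$weights, digits))
  invisible(x)
}
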