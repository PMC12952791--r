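# Native tree ensembles backing the behavior classifiers.
#
# One compiled regression-tree learner (see src/trees.cpp) supports all
# three algorithms:
#   random_forest  - bagged probability trees (variance split = Gini on 0/1
#                    targets), per-node feature subsampling, leaf = class
#                    fraction, ensemble prob = mean over trees
#   gradient_boost - Newton boosting on logistic loss, shallow trees,
#                    learning rate 0.1 (scikit-learn-style defaults)
#   xgboost        - Newton boosting with L2 leaf regularization, deeper
#                    trees, learning rate 0.3 (xgboost-style defaults)
# All randomness flows through R's RNG, so set.seed() makes fits exact.

#' Ensemble hyperparameters
#'
#' Defaults mirror the conventional defaults of the corresponding reference
#' implementations where they translate to this engine.
#'
#' @param algorithm One of "random_forest", "gradient_boost", "xgboost".
#' @param n_estimators Number of trees.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param learning_rate Shrinkage for boosting (ignored by random_forest).
#' @param lambda L2 penalty on leaf values (boosting).
#' @param min_samples_leaf Minimum samples per leaf.
#' @param mtry Features tried per split; NULL = sqrt(p) for random_forest,
#'   all features for boosting.
#' @param subsample Row subsample fraction per boosting iteration.
#' @param bootstrap Bootstrap rows per tree (random_forest only).
#' @param class_weight "none" (default) or "balanced" (inverse-frequency
#'   sample weights).
#' @return A list of class `classifier_control`.
#' @export
classifier_control <- function(algorithm = "random_forest",
                               n_estimators = NULL, max_depth = NULL,
                               learning_rate = NULL, lambda = NULL,
                               min_samples_leaf = 1L, mtry = NULL,
                               subsample = 1, bootstrap = TRUE,
                               class_weight = c("none", "balanced")) {
  algorithm <- match.arg(algorithm,
                         c("random_forest", "gradient_boost", "xgboost"))
  defaults <- switch(algorithm,
    random_forest  = list(n_estimators = 100L, max_depth = 25L,
                          learning_rate = NA_real_, lambda = 0),
    gradient_boost = list(n_estimators = 100L, max_depth = 3L,
                          learning_rate = 0.1, lambda = 0),
    xgboost        = list(n_estimators = 100L, max_depth = 6L,
                          learning_rate = 0.3, lambda = 1))
  ctl <- list(algorithm = algorithm,
              n_estimators = as.integer(n_estimators %||% defaults$n_estimators),
              max_depth = as.integer(max_depth %||% defaults$max_depth),
              learning_rate = learning_rate %||% defaults$learning_rate,
              lambda = lambda %||% defaults$lambda,
              min_samples_leaf = as.integer(min_samples_leaf),
              mtry = mtry, subsample = subsample, bootstrap = bootstrap,
              class_weight = match.arg(class_weight))
  class(ctl) <- "classifier_control"
  ctl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_ensemble <- function(X, y, ctl, weights = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(weights)) weights <- rep(1, n)
  bins <- .make_bins(X, 256L)
  if (ctl$algorithm == "random_forest") {
    mtry <- ctl$mtry %||% max(1L, floor(sqrt(p)))
    trees <- vector("list", ctl$n_estimators)
    for (b in seq_len(ctl$n_estimators)) {
      rows <- if (ctl$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      trees[[b]] <- .tree_grow(bins$binned, bins$cuts, y * weights, weights,
                               rows - 1L, ctl$max_depth,
                               ctl$min_samples_leaf, 0, as.integer(mtry), 0)
    }
    list(trees = trees, type = "forest", base_score = NA_real_)
  } else {
    mtry <- ctl$mtry %||% p
    base <- log(mean(y) / (1 - mean(y)))
    f <- rep(base, n)
    trees <- vector("list", ctl$n_estimators)
    for (b in seq_len(ctl$n_estimators)) {
      prob <- 1 / (1 + exp(-f))
      g <- (y - prob) * weights
      h <- pmax(prob * (1 - prob), 1e-12) * weights
      rows <- if (ctl$subsample < 1)
        sort(sample.int(n, max(2L, round(ctl$subsample * n)))) else seq_len(n)
      tr <- .tree_grow(bins$binned, bins$cuts, g, h, rows - 1L, ctl$max_depth,
                       ctl$min_samples_leaf, 0, as.integer(mtry), ctl$lambda)
      f <- f + ctl$learning_rate * .tree_predict(tr, X)
      trees[[b]] <- tr
    }
    list(trees = trees, type = "boost", base_score = base,
         learning_rate = ctl$learning_rate)
  }
}

predict_ensemble <- function(ens, X) {
  if (ens$type == "forest") {
    acc <- numeric(nrow(X))
    for (tr in ens$trees) acc <- acc + .tree_predict(tr, X)
    pmin(1, pmax(0, acc / length(ens$trees)))
  } else {
    f <- rep(ens$base_score, nrow(X))
    for (tr in ens$trees) f <- f + ens$learning_rate * .tree_predict(tr, X)
    1 / (1 + exp(-f))
  }
}
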