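# Training, cross-validating, and applying behavior classifiers.
#
# A training dataset is a list of (FeatureMatrix, Ethogram) pairs, one per
# video. Only labeled (non-NA) frames on valid pose frames enter training;
# a fit requires at least 100 labeled frames across at least 2 videos, and
# both classes present.

MIN_LABELED_FRAMES <- 100L
MIN_VIDEOS <- 2L
CLF_FORMAT_VERSION <- "ethokit-clf-1"

check_dataset <- function(datasets) {
  if (!is.list(datasets) || length(datasets) == 0L)
    stop("datasets must be a non-empty list of (features, labels) pairs")
  for (d in datasets) {
    if (!inherits(d[[1]], "FeatureMatrix") || !inherits(d[[2]], "Ethogram"))
      stop("each dataset element must be list(features = FeatureMatrix, labels = Ethogram)")
    if (nrow(d[[1]]$values) != length(d[[2]]$labels))
      stop("feature matrix and ethogram disagree on frame count")
  }
  nms <- lapply(datasets, function(d) d[[1]]$feature_names)
  if (length(unique(nms)) != 1L)
    stop("all feature matrices must share the same feature set")
  invisible(datasets)
}

assemble_training <- function(datasets) {
  Xs <- list(); ys <- list(); vid <- list()
  for (i in seq_along(datasets)) {
    fm <- datasets[[i]][[1]]; e <- datasets[[i]][[2]]
    use <- !is.na(e$labels) & fm$valid_mask
    Xs[[i]] <- fm$values[use, , drop = FALSE]
    ys[[i]] <- e$labels[use]
    vid[[i]] <- rep(i, sum(use))
  }
  list(X = do.call(rbind, Xs), y = unlist(ys), video = unlist(vid))
}

fit_core <- function(X, y, ctl) {
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; both classes are required")
  w <- NULL
  if (ctl$class_weight == "balanced") {
    tab <- table(y)
    w <- as.numeric(length(y) / (2 * tab[as.character(y)]))
  }
  fit_ensemble(X, y, ctl, weights = w)
}

#' Train a behavior classifier
#'
#' @param datasets List of per-video pairs
#'   `list(features = FeatureMatrix, labels = Ethogram)`. Unlabeled (NA)
#'   frames and invalid pose frames are excluded.
#' @param algorithm "random_forest", "gradient_boost", or "xgboost".
#' @param seed Integer seed; fits are exactly reproducible given the seed.
#' @param control A [classifier_control()]; its `algorithm` is overridden by
#'   `algorithm`.
#' @return Object of class `ClassifierModel` with the fitted ensemble,
#'   feature list, window size, behavior name, a training summary
#'   (labeled-frame count, video count, class balance) and feature
#'   importances (total split gain per feature, normalized).
#' @export
train_classifier <- function(datasets, algorithm = "random_forest", seed = 1,
                             control = NULL) {
  check_dataset(datasets)
  ctl <- control %||% classifier_control(algorithm)
  ctl$algorithm <- match.arg(algorithm,
                             c("random_forest", "gradient_boost", "xgboost"))
  tr <- assemble_training(datasets)
  n_videos <- length(datasets)
  if (length(tr$y) < MIN_LABELED_FRAMES || n_videos < MIN_VIDEOS)
    stop(sprintf(paste0("training requires a minimum of %d labeled frames ",
                        "across a minimum of %d videos (got %d frames, ",
                        "%d videos)"),
                 MIN_LABELED_FRAMES, MIN_VIDEOS, length(tr$y), n_videos))
  set.seed(seed)
  ens <- fit_core(tr$X, tr$y, ctl)
  fm1 <- datasets[[1]][[1]]
  model <- structure(list(
    algorithm = ctl$algorithm,
    window_size = fm1$window_size,
    feature_names = fm1$feature_names,
    behavior_name = datasets[[1]][[2]]$behavior_name,
    ensemble = ens,
    control = ctl,
    training_summary = list(n_labeled_frames = length(tr$y),
                            n_videos = n_videos,
                            class_balance = mean(tr$y)),
    version = CLF_FORMAT_VERSION), class = "ClassifierModel")
  model$feature_importance <- feature_importance(model)
  model
}

#' @export
print.ClassifierModel <- function(x, ...) {
  s <- x$training_summary
  cat(sprintf(paste0("<ClassifierModel> '%s' (%s, w = %d)\n",
                     "  trained on %d labeled frames / %d videos ",
                     "(behavior fraction %.3f)\n"),
              x$behavior_name, x$algorithm, x$window_size,
              s$n_labeled_frames, s$n_videos, s$class_balance))
  invisible(x)
}

#' Feature importances of a fitted classifier
#'
#' Split-count based importance: the number of times each feature is used
#' for a split across the ensemble, normalized to sum to 1.
#'
#' @param model A `ClassifierModel`.
#' @return Named numeric vector over `feature_names`.
#' @export
feature_importance <- function(model) {
  counts <- numeric(length(model$feature_names))
  for (tr in model$ensemble$trees) {
    used <- tr$feature[tr$feature >= 0L] + 1L
    if (length(used)) {
      t2 <- tabulate(used, nbins = length(counts))
      counts <- counts + t2
    }
  }
  total <- sum(counts)
  imp <- if (total > 0) counts / total else counts
  names(imp) <- model$feature_names
  imp
}

#' Predict an ethogram from features
#'
#' @param object A `ClassifierModel`.
#' @param features A `FeatureMatrix` with the same `feature_names` the model
#'   was trained on.
#' @param threshold Probability decision threshold (default 0.5); a frame is
#'   behavior iff probability > threshold.
#' @param ... Unused.
#' @return An `Ethogram` with binary labels and per-frame probabilities.
#'   Invalid pose frames are predicted not_behavior with probability NA.
#' @export
predict.ClassifierModel <- function(object, features, threshold = 0.5, ...) {
  stopifnot(inherits(features, "FeatureMatrix"))
  if (!identical(features$feature_names, object$feature_names)) {
    missing_f <- setdiff(object$feature_names, features$feature_names)
    extra_f <- setdiff(features$feature_names, object$feature_names)
    stop("feature names do not match the model; missing: {",
         paste(missing_f, collapse = ", "), "}; unexpected: {",
         paste(extra_f, collapse = ", "), "}")
  }
  prob <- predict_ensemble(object$ensemble, features$values)
  lab <- as.integer(prob > threshold)
  lab[!features$valid_mask] <- 0L
  prob[!features$valid_mask] <- NA_real_
  ethogram(lab, probabilities = prob, fps = features$fps,
           behavior_name = object$behavior_name,
           source = paste0("classifier:", object$algorithm))
}

#' Grouped k-fold cross-validation
#'
#' Videos (not frames) are partitioned into `k` folds to avoid temporal
#' leakage between training and held-out frames of the same recording. Each
#' fold's held-out labeled frames are scored with frame accuracy, F1, and
#' AUROC.
#'
#' @inheritParams train_classifier
#' @param k Number of folds (`2 <= k <=` number of videos).
#' @return data.frame with one row per fold (fold, n_videos, n_frames,
#'   accuracy, F1, auroc) plus a `summary` attribute (mean and sd).
#' @export
cross_validate <- function(datasets, algorithm = "random_forest", k = 5,
                           seed = 1, control = NULL) {
  check_dataset(datasets)
  n_videos <- length(datasets)
  if (k < 2) stop("k must be >= 2")
  if (k > n_videos)
    stop("cannot make ", k, " folds from ", n_videos, " videos")
  ctl <- control %||% classifier_control(algorithm)
  ctl$algorithm <- match.arg(algorithm,
                             c("random_forest", "gradient_boost", "xgboost"))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(k), n_videos))
  rows <- list()
  for (fold in seq_len(k)) {
    train_sets <- datasets[fold_of != fold]
    test_sets <- datasets[fold_of == fold]
    tr <- assemble_training(train_sets)
    ens <- fit_core(tr$X, tr$y, ctl)
    te <- assemble_training(test_sets)
    prob <- predict_ensemble(ens, te$X)
    pred <- as.integer(prob > 0.5)
    fm <- frame_metrics(te$y, pred)
    auroc <- if (length(unique(te$y)) == 2L)
      roc_metrics(prob, te$y)$auroc else NA_real_
    rows[[fold]] <- data.frame(fold = fold, n_videos = length(test_sets),
                               n_frames = length(te$y),
                               accuracy = fm$accuracy, F1 = fm$F1,
                               auroc = auroc)
  }
  out <- do.call(rbind, rows)
  mets <- c("accuracy", "F1", "auroc")
  attr(out, "summary") <- data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(out[[m]], na.rm = TRUE), 0),
    sd = vapply(mets, function(m) sd(out[[m]], na.rm = TRUE), 0))
  out
}

tree_to_list <- function(tr) {
  lapply(tr, function(v) unname(v))
}

#' Export / import a classifier archive
#'
#' The archive is a single JSON file embedding the format version,
#' algorithm, window size, feature list, behavior name, training summary,
#' hyperparameters, and the serialized ensemble. `import_classifier()`
#' restores a model whose predictions are identical to the original.
#'
#' @param model A `ClassifierModel`.
#' @param path Output file path.
#' @return `path` invisibly (export); a `ClassifierModel` (import).
#' @export
export_classifier <- function(model, path) {
  stopifnot(inherits(model, "ClassifierModel"))
  payload <- list(
    version = model$version,
    algorithm = model$algorithm,
    window_size = model$window_size,
    feature_names = model$feature_names,
    behavior_name = model$behavior_name,
    training_summary = model$training_summary,
    control = model$control[setdiff(names(model$control), "mtry")],
    mtry = model$control$mtry,
    ensemble = list(type = model$ensemble$type,
                    base_score = model$ensemble$base_score,
                    learning_rate = model$ensemble$learning_rate,
                    trees = lapply(model$ensemble$trees, tree_to_list)))
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname export_classifier
#' @export
import_classifier <- function(path) {
  if (!file.exists(path)) stop("classifier archive not found: ", path)
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyDataFrame = FALSE)
  if (is.null(payload$version) || !identical(payload$version,
                                             CLF_FORMAT_VERSION))
    stop("classifier archive version mismatch (expected ",
         CLF_FORMAT_VERSION, ")")
  req <- c("algorithm", "window_size", "feature_names", "behavior_name",
           "training_summary", "ensemble")
  miss <- req[!req %in% names(payload)]
  if (length(miss))
    stop("classifier archive missing metadata: ", paste(miss, collapse = ", "))
  trees <- lapply(payload$ensemble$trees, function(tr) {
    list(feature = as.integer(unlist(tr$feature)),
         threshold = as.numeric(unlist(tr$threshold)),
         left = as.integer(unlist(tr$left)),
         right = as.integer(unlist(tr$right)),
         value = as.numeric(unlist(tr$value)))
  })
  ens <- list(trees = trees, type = payload$ensemble$type,
              base_score = payload$ensemble$base_score %||% NA_real_,
              learning_rate = payload$ensemble$learning_rate)
  ctl <- payload$control
  ctl$mtry <- payload$mtry
  class(ctl) <- "classifier_control"
  model <- structure(list(
    algorithm = payload$algorithm,
    window_size = as.integer(payload$window_size),
    feature_names = as.character(unlist(payload$feature_names)),
    behavior_name = payload$behavior_name,
    ensemble = ens,
    control = ctl,
    training_summary = payload$training_summary,
    version = payload$version), class = "ClassifierModel")
  model$feature_importance <- feature_importance(model)
  model
}
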