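small_rf <- classifier_control("random_forest", n_estimators = 30)
small_xgb <- classifier_control("xgboost", n_estimators = 30)

test_that("training enforces the 100-frame / 2-video minimum", {
  ds <- separable_dataset(n_videos = 3, n_frames = 33)   # 99 labeled frames
  expect_error(train_classifier(ds, "random_forest"),
               "minimum of 100 labeled frames")
  ds1 <- separable_dataset(n_videos = 1, n_frames = 500)
  expect_error(train_classifier(ds1, "random_forest"), "2 videos")

  # single-class labels are rejected
  ds2 <- separable_dataset(n_videos = 2, n_frames = 100)
  for (i in 1:2) ds2[[i]]$labels <- ethogram(rep(1L, 100))
  expect_error(train_classifier(ds2, "random_forest"), "single class")
})

test_that("separable data is fit perfectly and deterministically", {
  ds <- separable_dataset(n_videos = 2, n_frames = 200, seed = 2)
  for (algo in c("random_forest", "gradient_boost", "xgboost")) {
    m <- train_classifier(ds, algo, seed = 5,
                          control = classifier_control(algo, n_estimators = 30))
    for (d in ds) {
      pred <- predict(m, d$features)
      expect_equal(frame_metrics(d$labels, pred)$accuracy, 1,
                   info = algo)
    }
  }
  # same data + same seed -> identical held-out predictions
  heldout <- separable_dataset(n_videos = 1, n_frames = 300, seed = 9)[[1]]
  m1 <- train_classifier(ds, "random_forest", seed = 11, control = small_rf)
  m2 <- train_classifier(ds, "random_forest", seed = 11, control = small_rf)
  expect_identical(predict(m1, heldout$features)$probabilities,
                   predict(m2, heldout$features)$probabilities)
  expect_equal(m1$training_summary$n_labeled_frames, 400)
  expect_equal(m1$training_summary$n_videos, 2)
  expect_true(abs(sum(m1$feature_importance) - 1) < 1e-9)
})

test_that("a deep unconstrained forest memorizes its training labels", {
  set.seed(30)
  n <- 240
  x <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, 0.5)
  fm <- feature_matrix(x, paste0("f", 1:5), fps = 30)
  ds <- list(list(features = fm, labels = ethogram(y)),
             list(features = fm, labels = ethogram(y)))
  m <- train_classifier(ds, "random_forest", seed = 3,
                        control = classifier_control("random_forest",
                                                     n_estimators = 50,
                                                     max_depth = 30,
                                                     mtry = 5,
                                                     bootstrap = FALSE))
  pred <- predict(m, fm)
  expect_equal(pred$labels, y)
  # probability/label consistency at the 0.5 threshold
  expect_equal(pred$labels, as.integer(pred$probabilities > 0.5))
})

test_that("prediction validates feature names and masks invalid frames", {
  ds <- separable_dataset(n_videos = 2, n_frames = 100, seed = 4)
  m <- train_classifier(ds, "random_forest", seed = 1, control = small_rf)
  wrong <- feature_matrix(ds[[1]]$features$values,
                          c("f1", "other"), fps = 30)
  expect_error(predict(m, wrong), "other")

  fm <- ds[[1]]$features
  fm$valid_mask[1:10] <- FALSE
  pred <- predict(m, fm)
  expect_true(all(pred$labels[1:10] == 0L))
  expect_true(all(is.na(pred$probabilities[1:10])))
  expect_true(all(!is.na(pred$probabilities[-(1:10)])))
})

test_that("grouped cross-validation scores separable data and nulls correctly", {
  ds <- separable_dataset(n_videos = 6, n_frames = 120, seed = 6)
  cv <- cross_validate(ds, "random_forest", k = 3, seed = 2,
                       control = small_rf)
  expect_equal(nrow(cv), 3)
  expect_gte(mean(cv$accuracy), 0.95)

  # permuted labels: AUROC near chance
  set.seed(7)
  null_ds <- lapply(ds, function(d) {
    d$labels <- ethogram(sample(d$labels$labels))
    d
  })
  cv0 <- cross_validate(null_ds, "random_forest", k = 3, seed = 2,
                        control = small_rf)
  expect_lt(abs(mean(cv0$auroc) - 0.5), 0.1)

  expect_error(cross_validate(ds, "random_forest", k = 7), "folds")
})

test_that("export/import round-trips prediction behavior and metadata", {
  ds <- lapply(1:2, function(s) turn_video(s, n_frames = 400, w = 5))
  te <- turn_video(99, n_frames = 300, w = 5)
  m <- train_classifier(ds, "xgboost", seed = 8, control = small_xgb)
  path <- withr::local_tempfile(fileext = ".clf")
  export_classifier(m, path)
  m2 <- import_classifier(path)
  expect_identical(predict(m2, te$features)$labels,
                   predict(m, te$features)$labels)
  expect_equal(predict(m2, te$features)$probabilities,
               predict(m, te$features)$probabilities, tolerance = 1e-12)
  expect_identical(m2$window_size, 5L)
  expect_identical(m2$algorithm, "xgboost")
  expect_identical(m2$behavior_name, m$behavior_name)

  # archives from two different window sizes keep their w
  ds0 <- lapply(1:2, function(s) turn_video(s, n_frames = 400, w = 0))
  m0 <- train_classifier(ds0, "xgboost", seed = 8, control = small_xgb)
  p0 <- withr::local_tempfile(fileext = ".clf")
  export_classifier(m0, p0)
  expect_identical(import_classifier(p0)$window_size, 0L)

  # corrupt archive: missing feature list
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyDataFrame = FALSE)
  payload$feature_names <- NULL
  bad <- withr::local_tempfile(fileext = ".clf")
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), bad)
  expect_error(import_classifier(bad), "feature_names")
  payload$version <- "ethokit-clf-0"
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), bad)
  expect_error(import_classifier(bad), "version")
})
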