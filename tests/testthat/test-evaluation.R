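test_that("report matches the hand-computed 2x2 example", {
  y_true <- c(0L, 0L, 1L, 1L)
  y_pred <- c(0L, 1L, 1L, 1L)
  r <- classification_report(y_true, y_pred, 2)
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$per_class$precision, c(1, 2 / 3))
  expect_equal(r$per_class$recall, c(0.5, 1))
  expect_equal(r$per_class$f1, c(2 / 3, 0.8))
  expect_equal(unname(r$confusion), rbind(c(1L, 1L), c(0L, 2L)))
})

test_that("perfect predictions give all-ones metrics and a diagonal confusion", {
  y <- rep(0:3, times = c(5, 3, 4, 2))
  r <- classification_report(y, y, 4)
  expect_equal(r$accuracy, 1)
  expect_equal(r$per_class$precision, rep(1, 4))
  expect_equal(r$per_class$f1, rep(1, 4))
  cm <- confusion_matrix(y, y, 4)
  expect_equal(diag(cm), c(`0` = 5L, `1` = 3L, `2` = 4L, `3` = 2L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
})

test_that("micro recall equals accuracy and weighted averages recompute exactly", {
  set.seed(12)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    n <- sample(20:200, 1)
    y_true <- sample(0:(k - 1), n, replace = TRUE)
    y_pred <- sample(0:(k - 1), n, replace = TRUE)
    r <- suppressWarnings(classification_report(y_true, y_pred, k))
    # micro recall: support-weighted recall is sum(TP)/n = accuracy
    expect_equal(r$weighted$recall, r$accuracy)
    # report's own averages recompute from its per-class cells
    expect_equal(r$weighted$precision,
                 weighted_metric(r$per_class$precision, r$per_class$support))
    expect_equal(r$macro$f1, mean(r$per_class$f1))
    # supports conserve rows; confusion row sums equal supports
    expect_equal(sum(r$per_class$support), n)
    expect_equal(unname(rowSums(r$confusion)), r$per_class$support)
  }
})

test_that("zero-denominator metrics come back as 0 with a warning", {
  # class 1 never predicted: precision undefined
  expect_warning(r <- classification_report(c(0L, 1L), c(0L, 0L), 2),
                 "precision")
  expect_equal(r$per_class$precision[2], 0)
  expect_error(confusion_matrix(c(0L, 5L), c(0L, 1L), 2), "out of range")
  expect_error(classification_report(0L, c(0L, 1L), 2), "equal length")
})

test_that("display rounding is half away from zero at two decimals", {
  expect_equal(round_half_up(0.955, 2), 0.96)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(c(0.414, 0.415, 0.425), 2),
               c(0.41, 0.42, 0.43))
})

test_that("k-fold scores on a 4-row toy match exhaustive hand evaluation", {
  # majority baseline on 2 classes, 2 folds: each fold trains on one row
  # per class and scores the held-out pair
  tab <- feature_table(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                       c(0L, 0L, 1L, 1L), c("a", "b"))
  cv <- kfold_cv(classifier_spec("majority"), tab, k = 2, seed = 1,
                 normalize = FALSE)
  folds <- rflhar:::stratified_folds(tab$labels, 2, seed = 1)
  manual <- vapply(1:2, function(f) {
    tr <- ft_subset(tab, folds != f); te <- ft_subset(tab, folds == f)
    cnt <- tabulate(tr$labels + 1L, 2)
    pred <- which.max(cnt) - 1L
    mean(pred == te$labels)
  }, 0)
  expect_equal(cv$fold_accuracy, manual)
  expect_equal(cv$mean, mean(manual))

  # constant labels with the majority model: mean 1, sd 0
  ctab <- feature_table(matrix(rnorm(20), 10, 2), rep(0L, 10), c("a", "b"))
  ccv <- kfold_cv(classifier_spec("majority"), ctab, k = 2, seed = 2,
                  normalize = FALSE)
  expect_equal(ccv$mean, 1)
  expect_equal(ccv$sd, 0)

  expect_error(kfold_cv(classifier_spec("majority"), tab, k = 3, seed = 1),
               "fewer than")
})

test_that("runtime log records stages in order and can be disabled", {
  runtime_log_records(clear = TRUE)
  runtime_log("train", 1.5)
  runtime_log("evaluate", 0.2)
  recs <- runtime_log_records()
  expect_length(recs, 2L)
  expect_identical(recs[[1]]$stage, "train")
  expect_identical(recs[[2]]$stage, "evaluate")
  prev <- runtime_log_enable(FALSE)
  runtime_log("ignored", 9)
  expect_length(runtime_log_records(), 2L)
  runtime_log_enable(prev)
  runtime_log_records(clear = TRUE)
})
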