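test_that("transfer matrix is [RF probabilities | LSTM states] of width K+H", {
  tab <- small_table(300, seed = 1)
  cfg <- rfl_config(hidden_size = 32, epochs = 1)
  tf <- rfl_transform(tab, config = cfg, mode = "in_sample")
  expect_equal(ncol(tf$features), 8 + 32)
  expect_identical(colnames(tf$features)[1:8], paste0("rf_p", 0:7))
  expect_identical(colnames(tf$features)[9], "lstm_h0")
  expect_equal(unname(rowSums(tf$features[, 1:8])), rep(1, 300),
               tolerance = 1e-9)
  expect_true(all(is.finite(tf$features)))
})

test_that("disabling the temporal block reduces the transform to RF probabilities", {
  tab <- small_table(200, seed = 2)
  cfg <- rfl_config(hidden_size = 0)
  tf <- rfl_transform(tab, config = cfg, mode = "in_sample")
  ex <- fit_rf_extractor(tab, seed = cfg$rf_seed, class_count = 8)
  expect_equal(tf$features, rf_probability_features(ex, tab))
})

test_that("out-of-fold probabilities equal a brute-force refit on complementary halves", {
  # label a deterministic function of feature 1; 2 folds
  set.seed(3)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- as.integer(X[, 1] > 0)
  tab <- feature_table(X, y, c("a", "b", "c"))
  cfg <- rfl_config(hidden_size = 0, n_trees = 5, rf_seed = 11)
  tf <- rfl_transform(tab, config = cfg, mode = "out_of_fold", oof_folds = 2)

  folds <- rflhar:::stratified_folds(tab$labels, 2, seed = cfg$rf_seed)
  manual <- matrix(NA_real_, 60, 2)
  for (f in 1:2) {
    hold <- which(folds == f)
    ex <- fit_rf_extractor(ft_subset(tab, folds != f), n_trees = 5,
                           seed = 11, class_count = 2)
    manual[hold, ] <- rf_probability_features(ex, ft_subset(tab, hold))
  }
  expect_equal(unname(tf$features), manual)
})

test_that("out-of-fold mode refuses a target other than the training table", {
  tab <- small_table(100, seed = 4)
  other <- small_table(100, seed = 5)
  expect_error(rfl_transform(tab, other, mode = "out_of_fold"),
               "training matrix")
})

test_that("in-sample training features inflate accuracy relative to out-of-fold", {
  # the quantified leakage demonstration: same data, same classifier; the
  # in-sample path evaluates on features its extractor memorized
  spec <- sim_spec(templates = default_templates(gap = 0.25), noise_sd = 0.8)
  tab <- generate_dataset(spec, 600, seed = 6)
  cfg <- rfl_config(hidden_size = 0)
  ins <- rfl_transform(tab, config = cfg, mode = "in_sample")
  oof <- rfl_transform(tab, config = cfg, mode = "out_of_fold", oof_folds = 5)
  spec_cl <- classifier_spec("rf")
  m_ins <- train_classifier(spec_cl, as_feature_table(ins, tab$labels))
  acc_ins <- mean(predict(m_ins, ins$features) == tab$labels)
  # OOF accuracy read the honest way: 5-fold CV with per-fold features
  cv <- kfold_cv(spec_cl, tab, k = 5, seed = 6, use_rfl = TRUE,
                 rfl_cfg = cfg, normalize = FALSE)
  expect_gte(acc_ins, cv$mean)
  expect_gt(acc_ins - cv$mean, 0.01)  # the gap is material, not a tie
})

test_that("held-out featurization takes features only and matches train-time columns", {
  tab <- small_table(200, seed = 7)
  sp <- stratified_split(tab, 0.2, seed = 7)
  cfg <- rfl_config(hidden_size = 4, epochs = 1)
  tf <- rfl_transform(sp$train, config = cfg, mode = "in_sample")
  te <- rfl_apply(tf, sp$test$features)
  expect_identical(colnames(te), colnames(tf$features))
  expect_equal(nrow(te), ft_nrow(sp$test))
  # OOF transforms carry no extractors to apply elsewhere
  oof <- rfl_transform(sp$train, config = rfl_config(hidden_size = 0),
                       mode = "out_of_fold")
  expect_error(rfl_apply(oof, sp$test$features), "out-of-fold")
})

test_that("transfer features export through the table writer", {
  tab <- small_table(50, seed = 8)
  tf <- rfl_transform(tab, config = rfl_config(hidden_size = 2, epochs = 0),
                      mode = "in_sample")
  tmp <- tempfile(fileext = ".csv")
  write_transfer_features(tf, tab$labels, tmp)
  back <- read_feature_table(tmp)
  expect_identical(back$feature_names, colnames(tf$features))
  expect_equal(back$features, tf$features, tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(tmp)
})
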