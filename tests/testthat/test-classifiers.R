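test_that("GNB moments match hand-computed values on the two-blob toy", {
  X <- rbind(c(0, 0), c(2, 2), c(10, 10), c(12, 12))
  y <- c(0L, 0L, 1L, 1L)
  g <- fit_gnb(X, y, 2)
  expect_equal(g$mu, rbind(c(1, 1), c(11, 11)))
  expect_equal(g$var_raw, rbind(c(1, 1), c(1, 1)))  # ML variance, n in the denominator
  expect_equal(g$priors, c(0.5, 0.5))
  # likelihood comparison by hand: (1,1) is class 0's mean
  m <- train_classifier(classifier_spec("gnb"),
                        feature_table(X, y, c("a", "b")))
  expect_identical(predict(m, rbind(c(1, 1))), 0L)
  expect_identical(predict(m, rbind(c(11, 11))), 1L)
})

test_that("Gaussian feature likelihood matches the closed form", {
  expect_equal(gnb_feature_likelihood(0, 0, 1), 1 / sqrt(2 * pi))
  expect_equal(gnb_feature_likelihood(3, 3, 1 / (2 * pi)), 1)
  # monotone decay in |x - mu|
  xs <- seq(0, 6, by = 0.5)
  d <- gnb_feature_likelihood(xs, 0, 2)
  expect_true(all(diff(d) < 0))
  expect_error(gnb_feature_likelihood(0, 0, 0), "var")
})

test_that("native GNB probabilities agree with the reference backend", {
  # expected values frozen from scikit-learn GaussianNB (var_smoothing
  # 1e-9) run on this exact seeded fixture
  set.seed(42)
  n <- 60; p <- 4
  y <- rep(0:2, each = 20)
  X <- matrix(rnorm(n * p), n, p) + y * 0.8
  probe <- matrix(rnorm(5 * p), 5, p) + c(0, 1, 2, 0, 1) * 0.8
  m <- train_classifier(classifier_spec("gnb"),
                        feature_table(X, y, paste0("f", 1:4)))
  got <- predict_proba(m, probe)
  want <- rbind(
    c(0.730412432921, 0.269557727047, 0.000029840032),
    c(0.070451649421, 0.676046492613, 0.253501857966),
    c(0.010056064291, 0.194585540163, 0.795358395546),
    c(0.549819160939, 0.449652279070, 0.000528559992),
    c(0.330448868597, 0.574766474265, 0.094784657138))
  expect_equal(unname(got), want, tolerance = 1e-6)
})

test_that("logistic probability implements the closed form", {
  expect_equal(lr_probability(numeric(0), 0), 0.5)
  expect_equal(lr_probability(numeric(0), log(3)), 0.75)
  expect_equal(lr_probability(c(1, 2), 0.5, c(-0.5, 1)), plogis(2))
  # monotone in beta1 * x1
  b1 <- seq(-2, 2, by = 0.25)
  probs <- vapply(b1, function(b) lr_probability(1, 0, b), 0)
  expect_true(all(diff(probs) > 0))
  expect_error(lr_probability(c(1, 2), 0, 1), "same length")
})

test_that("reference defaults are honored and seeded fits reproduce", {
  spec <- classifier_spec("rf")
  expect_equal(spec$hyperparameters$n_trees, 10)
  expect_equal(spec$hyperparameters$max_depth, 10)
  expect_equal(spec$hyperparameters$criterion, "entropy")
  expect_identical(spec$seed, 0L)
  expect_equal(classifier_spec("gnb")$hyperparameters$var_smoothing, 1e-9)
  expect_equal(classifier_spec("lr")$hyperparameters$C, 1.0)
  expect_equal(classifier_spec("lr")$hyperparameters$max_iter, 200)
  expect_error(classifier_spec("rf", bogus = 1), "unknown hyperparameter")

  tab <- small_table(300, seed = 9)
  m <- train_classifier(spec, tab)
  expect_length(m$fit$trees, 10L)
  probe <- matrix(rnorm(20 * 9), 20, 9)
  for (kind in c("rf", "lr")) {
    a <- predict_proba(train_classifier(classifier_spec(kind), tab), probe)
    b <- predict_proba(train_classifier(classifier_spec(kind), tab), probe)
    expect_identical(a, b)
  }
})

test_that("decision tree memorizes separable data; all models normalize probabilities", {
  toy <- toy_blobs(25, seed = 10)
  dt <- train_classifier(classifier_spec("dt"), toy)
  expect_equal(mean(predict(dt, toy) == toy$labels), 1.0)

  tab <- small_table(300, seed = 11)
  probe <- matrix(rnorm(40 * 9), 40, 9)
  for (kind in c("rf", "dt", "lr", "gnb")) {
    m <- train_classifier(classifier_spec(kind), tab)
    P <- predict_proba(m, probe)
    expect_equal(unname(rowSums(P)), rep(1, 40), tolerance = 1e-9,
                 info = kind)
  }
  expect_error(train_classifier(classifier_spec("rf"),
                                feature_table(matrix(0, 4, 2), rep(0L, 4),
                                              c("a", "b"))),
               "single class")
})

test_that("probability ties break to the lowest class index", {
  stub <- rflhar:::rf_extractor_from_stubs(list(c(0.5, 0.5, 0)))
  P <- rf_probability_features(stub, matrix(0, 3, 2))
  expect_identical(rflhar:::argmax_class(P), rep(0L, 3))
  # majority baseline ties also resolve low
  tab <- feature_table(matrix(0, 4, 2), c(0L, 0L, 1L, 1L), c("a", "b"))
  m <- train_classifier(classifier_spec("majority"), tab)
  expect_identical(predict(m, matrix(0, 2, 2)), rep(0L, 2))
})
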