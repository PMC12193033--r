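# scalar reference implementation of the gate equations, H = 1, written
# against the printed formulas and independent of the package's batched code
scalar_lstm_step <- function(x, h, c, wf, wi, wc, wo, bf, bi, bc, bo) {
  s <- function(z) 1 / (1 + exp(-z))
  z <- c(h, x)
  f <- s(sum(wf * z) + bf)
  i <- s(sum(wi * z) + bi)
  g <- tanh(sum(wc * z) + bc)
  cn <- f * c + i * g
  o <- s(sum(wo * z) + bo)
  list(h = o * tanh(cn), c = cn)
}

test_that("zero parameters give the documented fixed point", {
  ex <- zero_lstm(hidden = 3, d = 2)
  st <- lstm_cell_step(c(0.4, -1.2), rep(0, 3), rep(0, 3), ex$params)
  expect_equal(st$f, rep(0.5, 3))
  expect_equal(st$i, rep(0.5, 3))
  expect_equal(st$o, rep(0.5, 3))
  expect_equal(st$c, rep(0, 3))
  expect_equal(st$h, rep(0, 3))
})

test_that("saturated gates reach the tanh(1) limit", {
  # forget closed, input/output/candidate saturated open: c -> 1,
  # h -> tanh(1), independent of the previous cell state
  ex <- zero_lstm(hidden = 2, d = 2)
  ex$params$bf <- rep(-50, 2)
  ex$params$bi <- rep(50, 2)
  ex$params$bo <- rep(50, 2)
  ex$params$bc <- rep(50, 2)
  st <- lstm_cell_step(c(1, 1), rep(0, 2), c(5, -3), ex$params)
  expect_equal(st$c, c(1, 1), tolerance = 1e-12)
  expect_equal(st$h, rep(tanh(1), 2), tolerance = 1e-12)
})

test_that("batched cell equals the scalar oracle over random draws", {
  set.seed(7)
  for (rep in 1:1000) {
    w <- rnorm(8); b <- rnorm(4); x <- rnorm(1); h <- rnorm(1); c <- rnorm(1)
    params <- list(Wf = matrix(w[1:2], 2, 1), Wi = matrix(w[3:4], 2, 1),
                   Wc = matrix(w[5:6], 2, 1), Wo = matrix(w[7:8], 2, 1),
                   bf = b[1], bi = b[2], bc = b[3], bo = b[4])
    got <- lstm_cell_step(x, h, c, params)
    want <- scalar_lstm_step(x, h, c, w[1:2], w[3:4], w[5:6], w[7:8],
                             b[1], b[2], b[3], b[4])
    expect_equal(got$h, want$h, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
  }
})

test_that("cell rejects inconsistent shapes", {
  ex <- zero_lstm(hidden = 3, d = 2)
  expect_error(lstm_cell_step(c(1, 2, 3), rep(0, 3), rep(0, 3), ex$params),
               "shapes")
  expect_error(lstm_cell_step(c(1, 2), rep(0, 2), rep(0, 2), ex$params),
               "shapes")
})

test_that("window features with W_len = 1 equal one cell step from zero state", {
  tab <- small_table(50, seed = 5)
  ex <- fit_lstm_extractor(tab, hidden_size = 4, window_len = 1, epochs = 1,
                           seed = 2)
  F <- lstm_temporal_features(ex, tab)
  manual <- t(apply(tab$features, 1, function(x) {
    lstm_cell_step(x, rep(0, 4), rep(0, 4), ex$params)$h
  }))
  expect_equal(unname(F), unname(manual), tolerance = 1e-12)

  # zero parameters, W_len = 1: every feature row is the zero vector
  z <- zero_lstm(hidden = 3, d = 9)
  Fz <- lstm_temporal_features(z, tab)
  expect_equal(unname(Fz), matrix(0, 50, 3))

  # duplicate inputs give identical features
  dup <- feature_table(tab$features[c(1, 1), ], tab$labels[c(1, 1)])
  Fd <- lstm_temporal_features(ex, dup)
  expect_identical(Fd[1, ], Fd[2, ])
})

test_that("epochs = 0 returns a usable seeded initialization", {
  tab <- small_table(40, seed = 6)
  ex <- fit_lstm_extractor(tab, hidden_size = 5, epochs = 0, seed = 3)
  expect_identical(ex$epochs_trained, 0L)
  F <- lstm_temporal_features(ex, tab)
  expect_equal(dim(F), c(40L, 5L))
  expect_true(all(is.finite(F)))
  ex2 <- fit_lstm_extractor(tab, hidden_size = 5, epochs = 0, seed = 3)
  expect_identical(ex$params, ex2$params)
})

test_that("training separates a 2-class problem and is reproducible", {
  spec <- sim_spec(templates = default_templates(k = 2),
                   class_proportions = c(0.5, 0.5))
  tab <- generate_dataset(spec, 400, seed = 8)
  nz <- fit_normalizer(tab)
  tab <- apply_normalizer(nz, tab)
  ex <- fit_lstm_extractor(tab, hidden_size = 8, epochs = 5, seed = 4)
  expect_gt(ex$train_accuracy, 0.9)
  ex2 <- fit_lstm_extractor(tab, hidden_size = 8, epochs = 5, seed = 4)
  expect_identical(ex$params, ex2$params)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(9)
  d <- 2; h <- 3; n <- 4; Tt <- 3
  ex <- lstm_init(d, h, class_count = 2, window_len = Tt, seed = 10)
  M <- matrix(rnorm(n * d), n, d)
  win <- rflhar:::window_indices(n, Tt)
  y1h <- matrix(0, n, 2); y1h[cbind(1:n, sample(1:2, n, TRUE))] <- 1
  params <- ex$params
  loss_at <- function(p) {
    fw <- rflhar:::lstm_forward(p, M, win)
    P <- rflhar:::softmax_rows(sweep(fw$h %*% p$Wy, 2, p$by, "+"))
    -mean(log(rowSums(P * y1h) + 1e-12))
  }
  fw <- rflhar:::lstm_forward(params, M, win, keep_cache = TRUE)
  bk <- rflhar:::lstm_backward(params, fw, win, M, y1h)
  eps <- 1e-6
  for (nm in c("Wf", "Wc", "Wy", "bf", "bo")) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (j in idx) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(bk$grads[[nm]][j], num, tolerance = 1e-4)
    }
  }
})

test_that("window_len larger than the table is rejected", {
  tab <- small_table(10, seed = 1)
  expect_error(fit_lstm_extractor(tab, window_len = 11), "window_len")
})
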