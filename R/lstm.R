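# Single-layer LSTM temporal-feature extractor, implemented natively.
#
# The cell follows the standard gate formulation on the concatenated
# [h_{t-1}, x_t] input:
#
#   f_t = sigmoid(W_f [h_{t-1}, x_t] + b_f)        forget gate
#   i_t = sigmoid(W_i [h_{t-1}, x_t] + b_i)        input gate
#   g_t = tanh   (W_C [h_{t-1}, x_t] + b_C)        candidate cell state
#   C_t = f_t * C_{t-1} + i_t * g_t                cell state
#   o_t = sigmoid(W_o [h_{t-1}, x_t] + b_o)        output gate
#   h_t = o_t * tanh(C_t)                          hidden state
#
# Training attaches a softmax classification head to the final hidden state
# of each window (supervision = the window's last-row label, categorical
# cross-entropy, Adam). After training the head is kept only for
# diagnostics; the H-dimensional final hidden state h_T is the temporal
# transfer feature for a row.
#
# Weight matrices are stored transposed relative to the column-vector
# notation above, as (H + D) x H blocks applied by right-multiplication, so
# a whole minibatch advances with four matrix products per time step.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize LSTM extractor parameters
#'
#' Uniform initialization in `[-r, r]` with `r = 1/sqrt(H + D)`; the forget
#' gate bias starts at 1 (the usual remember-by-default initialization).
#'
#' @param input_dim number of input channels D (default 9).
#' @param hidden_size hidden units H (default 32).
#' @param class_count classes K for the softmax head (default 8).
#' @param window_len rows per input window (default 1; see
#'   [lstm_temporal_features()]).
#' @param seed integer seed.
#' @return an `lstm_extractor` with untrained parameters
#'   (`epochs_trained = 0`).
#' @export
lstm_init <- function(input_dim = 9, hidden_size = 32, class_count = 8,
                      window_len = 1, seed = 0) {
  stopifnot(hidden_size >= 1, input_dim >= 1, window_len >= 1)
  d <- as.integer(input_dim); h <- as.integer(hidden_size)
  r <- 1 / sqrt(h + d)
  mk <- function(nr, nc) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  params <- with_seed(seed, list(
    Wf = mk(h + d, h), Wi = mk(h + d, h), Wc = mk(h + d, h), Wo = mk(h + d, h),
    bf = rep(1, h), bi = rep(0, h), bc = rep(0, h), bo = rep(0, h),
    Wy = mk(h, class_count), by = rep(0, class_count)))
  structure(list(params = params, input_dim = d, hidden_size = h,
                 class_count = as.integer(class_count),
                 window_len = as.integer(window_len),
                 epochs_trained = 0L, seed = as.integer(seed),
                 train_accuracy = NA_real_),
            class = "lstm_extractor")
}

#' One LSTM cell step
#'
#' Pure function implementing the five gate equations and the state
#' updates. Accepts a single time step for one sample (vectors) or a
#' minibatch (matrices with one row per sample).
#'
#' @param x_t input at time t: length-D vector or `n x D` matrix.
#' @param h_prev,c_prev previous hidden/cell state: length-H vectors or
#'   `n x H` matrices.
#' @param params parameter list with `Wf, Wi, Wc, Wo` (`(H+D) x H`) and
#'   `bf, bi, bc, bo` (length H), e.g. `extractor$params`.
#' @return list with `h` and `c` (same shape as `h_prev`), plus the gate
#'   activations `f`, `i`, `g`, `o` used by backpropagation.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, params) {
  vec_in <- is.null(dim(x_t))
  X <- if (vec_in) matrix(x_t, nrow = 1) else as.matrix(x_t)
  H <- if (is.null(dim(h_prev))) matrix(h_prev, nrow = 1) else as.matrix(h_prev)
  C <- if (is.null(dim(c_prev))) matrix(c_prev, nrow = 1) else as.matrix(c_prev)
  hs <- ncol(H)
  if (nrow(params$Wf) != hs + ncol(X) || ncol(params$Wf) != hs ||
      !all(dim(H) == dim(C)) || nrow(X) != nrow(H)) {
    stop_arg("inconsistent shapes among x_t, states and parameters")
  }
  Z <- cbind(H, X)
  f <- sigmoid(sweep(Z %*% params$Wf, 2, params$bf, "+"))
  i <- sigmoid(sweep(Z %*% params$Wi, 2, params$bi, "+"))
  g <- tanh(sweep(Z %*% params$Wc, 2, params$bc, "+"))
  c_t <- f * C + i * g
  o <- sigmoid(sweep(Z %*% params$Wo, 2, params$bo, "+"))
  h_t <- o * tanh(c_t)
  if (vec_in) {
    list(h = drop(h_t), c = drop(c_t), f = drop(f), i = drop(i),
         g = drop(g), o = drop(o))
  } else {
    list(h = h_t, c = c_t, f = f, i = i, g = g, o = o)
  }
}

# Build the window index matrix: row r of the output lists the W_len source
# rows ending at r, repeat-padding the first row at the sequence start.
window_indices <- function(n, window_len) {
  idx <- sapply(seq_len(window_len), function(j) {
    pmax(1L, seq_len(n) - window_len + j)
  })
  matrix(as.integer(idx), nrow = n)
}

# forward pass over a batch of windows; X: n x D, win: n x T index matrix
# into X's origin table rows. Returns final h plus caches for BPTT.
lstm_forward <- function(params, M, win, keep_cache = FALSE) {
  n <- nrow(win); Tt <- ncol(win); h <- ncol(params$Wy)
  hs <- nrow(params$Wy)
  Hs <- matrix(0, n, hs); Cs <- matrix(0, n, hs)
  cache <- if (keep_cache) vector("list", Tt) else NULL
  for (t in seq_len(Tt)) {
    Xt <- M[win[, t], , drop = FALSE]
    st <- lstm_cell_step(Xt, Hs, Cs, params)
    if (keep_cache) {
      cache[[t]] <- list(Z = cbind(Hs, Xt), f = st$f, i = st$i, g = st$g,
                         o = st$o, c_prev = Cs, c = st$c)
    }
    Hs <- st$h; Cs <- st$c
  }
  list(h = Hs, cache = cache)
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# gradient of mean cross-entropy loss w.r.t. all parameters for one batch
lstm_backward <- function(params, fw, win, M, y_onehot) {
  n <- nrow(win); Tt <- ncol(win)
  hs <- nrow(params$Wy); d <- ncol(M)
  logits <- sweep(fw$h %*% params$Wy, 2, params$by, "+")
  P <- softmax_rows(logits)
  dL <- (P - y_onehot) / n
  grads <- list(Wy = t(fw$h) %*% dL, by = colSums(dL),
                Wf = 0 * params$Wf, Wi = 0 * params$Wi,
                Wc = 0 * params$Wc, Wo = 0 * params$Wo,
                bf = 0 * params$bf, bi = 0 * params$bi,
                bc = 0 * params$bc, bo = 0 * params$bo)
  dh <- dL %*% t(params$Wy)
  dc <- matrix(0, n, hs)
  for (t in rev(seq_len(Tt))) {
    cc <- fw$cache[[t]]
    tc <- tanh(cc$c)
    do <- dh * tc
    dc <- dc + dh * cc$o * (1 - tc^2)
    df <- dc * cc$c_prev
    di <- dc * cc$g
    dg <- dc * cc$i
    dc_prev <- dc * cc$f
    af <- df * cc$f * (1 - cc$f)
    ai <- di * cc$i * (1 - cc$i)
    ag <- dg * (1 - cc$g^2)
    ao <- do * cc$o * (1 - cc$o)
    Zt <- t(cc$Z)
    grads$Wf <- grads$Wf + Zt %*% af
    grads$Wi <- grads$Wi + Zt %*% ai
    grads$Wc <- grads$Wc + Zt %*% ag
    grads$Wo <- grads$Wo + Zt %*% ao
    grads$bf <- grads$bf + colSums(af)
    grads$bi <- grads$bi + colSums(ai)
    grads$bc <- grads$bc + colSums(ag)
    grads$bo <- grads$bo + colSums(ao)
    dZ <- af %*% t(params$Wf) + ai %*% t(params$Wi) +
      ag %*% t(params$Wc) + ao %*% t(params$Wo)
    dh <- dZ[, seq_len(hs), drop = FALSE]
    dc <- dc_prev
  }
  loss <- -mean(log(rowSums(P * y_onehot) + 1e-12))
  list(grads = grads, loss = loss)
}

#' Train the LSTM temporal-feature extractor
#'
#' Windows of `window_len` consecutive rows (edge-padded by repeating the
#' first row) are classified through a softmax head on the final hidden
#' state; the recurrent parameters after `epochs` of Adam are returned.
#' Training is seeded; bit-level reproducibility holds on a single platform
#' and BLAS.
#'
#' @param train a [feature_table()]; rows are taken in table order as the
#'   time axis.
#' @param hidden_size hidden units H (default 32).
#' @param window_len rows per window (default 1, so each row is its own
#'   length-1 sequence and row counts are preserved downstream).
#' @param epochs full passes over the windows (default 10); `epochs = 0`
#'   returns the seeded initialization untouched.
#' @param batch_size minibatch rows (default 256).
#' @param learning_rate Adam step size (default 0.01).
#' @param seed integer seed for initialization and shuffling.
#' @param class_count classes for the head; default inferred.
#' @return a fitted `lstm_extractor`; `$train_accuracy` holds the head's
#'   final training accuracy.
#' @export
fit_lstm_extractor <- function(train, hidden_size = 32, window_len = 1,
                               epochs = 10, batch_size = 256,
                               learning_rate = 0.01, seed = 0,
                               class_count = NULL) {
  stopifnot(inherits(train, "feature_table"), window_len >= 1)
  n <- ft_nrow(train)
  if (n == 0) stop_arg("train must be nonempty")
  if (window_len > n) {
    stop_arg("window_len (", window_len, ") exceeds the ", n,
             " available contiguous rows")
  }
  k <- if (is.null(class_count)) max(train$labels) + 1L else as.integer(class_count)
  ex <- lstm_init(ncol(train$features), hidden_size, k, window_len, seed)
  if (epochs == 0) return(ex)

  M <- train$features
  win <- window_indices(n, window_len)
  y1h <- matrix(0, n, k); y1h[cbind(seq_len(n), train$labels + 1L)] <- 1

  params <- ex$params
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  epoch_seeds <- derive_seeds(seed + 1L, epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(epoch_seeds[ep], sample.int(n))
    for (start in seq(1L, n, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, n)]
      fw <- lstm_forward(params, M, win[rows, , drop = FALSE],
                         keep_cache = TRUE)
      bk <- lstm_backward(params, fw, win[rows, , drop = FALSE], M,
                          y1h[rows, , drop = FALSE])
      step <- step + 1L
      for (nm in names(params)) {
        g <- bk$grads[[nm]]
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  ex$params <- params
  ex$epochs_trained <- as.integer(epochs)
  fw <- lstm_forward(params, M, win)
  pred <- argmax_class(softmax_rows(sweep(fw$h %*% params$Wy, 2,
                                          params$by, "+")))
  ex$train_accuracy <- mean(pred == train$labels)
  ex
}

#' LSTM temporal features
#'
#' For each row of `X`, runs the cell recurrence from the zero state over
#' the row's window (the row plus its `window_len - 1` predecessors in
#' table order, repeat-padded at the start) and returns the final hidden
#' state as that row's H temporal features. Deterministic given the
#' extractor's parameters.
#'
#' @param extractor a (possibly untrained) [fit_lstm_extractor()] result.
#' @param X a [feature_table()] or numeric matrix with D columns.
#' @return an `n x H` matrix with columns `lstm_h0..lstm_h{H-1}`.
#' @export
lstm_temporal_features <- function(extractor, X) {
  stopifnot(inherits(extractor, "lstm_extractor"))
  M <- if (inherits(X, "feature_table")) X$features else as.matrix(X)
  if (ncol(M) != extractor$input_dim) {
    stop_arg("input has ", ncol(M), " columns; extractor expects ",
             extractor$input_dim)
  }
  if (nrow(M) == 0) {
    out <- matrix(0, 0, extractor$hidden_size)
    colnames(out) <- paste0("lstm_h", seq_len(extractor$hidden_size) - 1L)
    return(out)
  }
  win <- window_indices(nrow(M), min(extractor$window_len, nrow(M)))
  h <- lstm_forward(extractor$params, M, win)$h
  colnames(h) <- paste0("lstm_h", seq_len(ncol(h)) - 1L)
  h
}
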