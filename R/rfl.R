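# Hybrid transfer features: random-forest class probabilities concatenated
# with LSTM final hidden states.
#
# The transform has two modes. `in_sample` fits both extractors on the full
# training table and applies them to any target matrix — the direct,
# replication-oriented path. `out_of_fold` applies only when the target IS
# the training table: rows receive features from extractors fitted on the
# complementary folds of a stratified partition, so no row's own label ever
# reaches the extractor that featurizes it. In-sample features of training
# rows are optimistically biased (the forest has effectively memorized
# them); the out-of-fold mode is the honest default whenever transfer
# features of the training partition feed a downstream fit that is then
# evaluated.

#' Configuration for the hybrid transfer-feature transform
#'
#' @param n_trees,max_depth,criterion,rf_seed forest settings
#'   (see [fit_rf_extractor()]); defaults 10, 10, `"entropy"`, 0.
#' @param hidden_size LSTM hidden units H (default 32); `0` disables the
#'   temporal block entirely.
#' @param window_len LSTM window length (default 1).
#' @param epochs LSTM training epochs (default 10).
#' @param batch_size,learning_rate LSTM optimizer settings.
#' @param lstm_seed seed for the LSTM (default 0).
#' @return a list of class `rfl_config`.
#' @export
rfl_config <- function(n_trees = 10, max_depth = 10, criterion = "entropy",
                       rf_seed = 0, hidden_size = 32, window_len = 1,
                       epochs = 10, batch_size = 256, learning_rate = 0.01,
                       lstm_seed = 0) {
  structure(list(n_trees = n_trees, max_depth = max_depth,
                 criterion = criterion, rf_seed = rf_seed,
                 hidden_size = hidden_size, window_len = window_len,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, lstm_seed = lstm_seed),
            class = "rfl_config")
}

fit_rfl_extractors <- function(train, config, class_count) {
  rf <- fit_rf_extractor(train, n_trees = config$n_trees,
                         max_depth = config$max_depth,
                         criterion = config$criterion,
                         seed = config$rf_seed, class_count = class_count)
  lstm <- if (config$hidden_size > 0) {
    fit_lstm_extractor(train, hidden_size = config$hidden_size,
                       window_len = config$window_len,
                       epochs = config$epochs,
                       batch_size = config$batch_size,
                       learning_rate = config$learning_rate,
                       seed = config$lstm_seed, class_count = class_count)
  } else {
    NULL
  }
  list(rf = rf, lstm = lstm)
}

apply_rfl_extractors <- function(extractors, X) {
  rf_block <- rf_probability_features(extractors$rf, X)
  if (is.null(extractors$lstm)) return(rf_block)
  cbind(rf_block, lstm_temporal_features(extractors$lstm, X))
}

#' Compute hybrid transfer features
#'
#' Produces the `n x (K + H)` matrix `[RF probabilities | LSTM hidden
#' states]`, in that fixed column order.
#'
#' @param train training [feature_table()] the extractors are fitted on.
#' @param X target [feature_table()] to featurize; defaults to `train`.
#'   Only `X$features` is read — labels of a held-out partition are never
#'   touched.
#' @param config an [rfl_config()].
#' @param mode `"out_of_fold"` (default; requires `X` to be `train` itself)
#'   or `"in_sample"`.
#' @param oof_folds stratified folds for out-of-fold extraction (default 5).
#' @param class_count classes K; default inferred from `train` labels.
#' @return a `transfer_features` object: `features` matrix with named
#'   columns (`rf_p0.., lstm_h0..`), `mode`, `class_count`, `hidden_size`,
#'   and (in-sample mode) the fitted `extractors` for reuse on held-out
#'   data.
#' @export
rfl_transform <- function(train, X = train, config = rfl_config(),
                          mode = c("out_of_fold", "in_sample"),
                          oof_folds = 5, class_count = NULL) {
  stopifnot(inherits(train, "feature_table"))
  mode <- match.arg(mode)
  k <- if (is.null(class_count)) max(train$labels) + 1L else as.integer(class_count)

  if (mode == "in_sample") {
    ex <- fit_rfl_extractors(train, config, k)
    feats <- apply_rfl_extractors(ex, X)
    return(structure(list(features = feats, mode = mode, class_count = k,
                          hidden_size = config$hidden_size,
                          extractors = ex),
                     class = "transfer_features"))
  }

  if (!identical(X$features, train$features)) {
    stop_arg("out_of_fold mode is defined only for the training matrix itself")
  }
  folds <- stratified_folds(train$labels, oof_folds, seed = config$rf_seed)
  feats <- matrix(NA_real_, ft_nrow(train),
                  k + max(0L, config$hidden_size))
  for (f in seq_len(oof_folds)) {
    hold <- which(folds == f)
    rest <- which(folds != f)
    ex <- fit_rfl_extractors(ft_subset(train, rest), config, k)
    block <- apply_rfl_extractors(ex, ft_subset(train, hold))
    feats[hold, ] <- block
    if (f == 1L) colnames(feats) <- colnames(block)
  }
  structure(list(features = feats, mode = mode, class_count = k,
                 hidden_size = config$hidden_size, extractors = NULL),
            class = "transfer_features")
}

#' Featurize held-out data with extractors fitted on training data
#'
#' Accepts a feature matrix only, so test labels cannot leak into the
#' transform by construction.
#'
#' @param tf an in-sample [rfl_transform()] result carrying extractors.
#' @param features numeric matrix of held-out rows (no labels).
#' @return transfer-feature matrix with the same columns as `tf$features`.
#' @export
rfl_apply <- function(tf, features) {
  stopifnot(inherits(tf, "transfer_features"))
  if (is.null(tf$extractors)) {
    stop_arg("transfer features were computed out-of-fold; refit in_sample ",
             "on the training table to featurize new data")
  }
  features <- as.matrix(features)
  ft <- feature_table(features, rep(0L, nrow(features)))
  apply_rfl_extractors(tf$extractors, ft)
}

# stratified fold assignment: per class, fold sizes by largest remainder,
# membership shuffled under the seed
stratified_folds <- function(labels, k_folds, seed = 0) {
  n <- length(labels)
  folds <- integer(n)
  classes <- sort(unique(labels))
  sub_seeds <- derive_seeds(seed + 104729L, length(classes))
  for (i in seq_along(classes)) {
    rows <- which(labels == classes[i])
    if (length(rows) < k_folds) {
      stop_arg("class ", classes[i], " has ", length(rows),
               " rows, fewer than ", k_folds, " folds")
    }
    sizes <- largest_remainder(length(rows), rep(1, k_folds))
    assign <- rep.int(seq_len(k_folds), sizes)
    rows <- with_seed(sub_seeds[i], sample(rows))
    folds[rows] <- assign
  }
  folds
}

#' Export transfer features through the table writer
#'
#' @param tf a [rfl_transform()] result.
#' @param labels labels to attach (same length as rows).
#' @param path destination file.
#' @param delimiter field separator.
#' @return invisibly, `path`.
#' @export
write_transfer_features <- function(tf, labels, path, delimiter = ",") {
  stopifnot(inherits(tf, "transfer_features"))
  write_feature_table(feature_table(tf$features, labels,
                                    colnames(tf$features)),
                      path, delimiter)
}

#' Convert transfer features to a feature table
#'
#' @param tf a [rfl_transform()] result.
#' @param labels labels to attach.
#' @return a [feature_table()].
#' @export
as_feature_table <- function(tf, labels) {
  stopifnot(inherits(tf, "transfer_features"))
  feature_table(tf$features, labels, colnames(tf$features))
}
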