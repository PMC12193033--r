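# Flat feature-table I/O, label bookkeeping, stratified splitting and
# leakage-safe normalization.

#' Ordered class names of the 8-exercise vocabulary
#'
#' Fixed index-to-name mapping for the eight therapy exercises (index 0..7).
#'
#' @return character vector of length 8.
#' @export
label_vocabulary <- function() {
  c("extended leg raises",
    "forward bending",
    "straight lying-leg raises",
    "side-lying hip abduction",
    "alternating leg lifts prone",
    "elbow flexion",
    "shoulder abduction",
    "prone lying elbow extension")
}

#' Construct a feature table
#'
#' The universal exchange object: an `n x 9` numeric sensor matrix plus one
#' 0-based integer class label per row.
#'
#' @param features numeric matrix (or data frame) of finite values.
#' @param labels integer class labels `0..K-1`, one per row.
#' @param feature_names column names; default the 9 IMU channels.
#' @return an object of class `feature_table` with fields `features`,
#'   `labels`, `feature_names`.
#' @export
feature_table <- function(features, labels,
                          feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop_arg("features and labels disagree on the number of rows")
  }
  if (nrow(features) > 0 && !all(is.finite(features))) {
    stop_arg("features must be finite")
  }
  if (length(labels) > 0 && any(labels < 0)) {
    stop_arg("labels must be nonnegative 0-based class indices")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) {
      feature_names <- if (ncol(features) == 9L) SENSOR_CHANNELS else
        paste0("f", seq_len(ncol(features)))
    }
  }
  stopifnot(length(feature_names) == ncol(features))
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels,
                 feature_names = feature_names),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  k <- if (length(x$labels)) max(x$labels) + 1L else 0L
  cat(sprintf("feature_table: %d rows x %d features, %d classes\n",
              nrow(x$features), ncol(x$features), k))
  invisible(x)
}

#' Number of rows of a feature table
#' @param table a [feature_table()].
#' @return integer row count.
#' @export
ft_nrow <- function(table) nrow(table$features)

#' Subset a feature table by row indices
#' @param table a [feature_table()].
#' @param idx integer row indices.
#' @return a [feature_table()].
#' @export
ft_subset <- function(table, idx) {
  feature_table(table$features[idx, , drop = FALSE], table$labels[idx],
                table$feature_names)
}

#' Row-bind two feature tables
#' @param a,b [feature_table()] objects with identical feature names.
#' @return a [feature_table()].
#' @export
ft_rbind <- function(a, b) {
  stopifnot(identical(a$feature_names, b$feature_names))
  feature_table(rbind(a$features, b$features), c(a$labels, b$labels),
                a$feature_names)
}

#' Read a delimited feature table
#'
#' Expects a header row, numeric feature columns and the label column last
#' (named `label`). A leading time-index column — named `time` or
#' `time_index` (case-insensitive), or forced via `has_time_index` — is
#' dropped: it carries no information about the performed exercise. Labels
#' may be 0-based integers or class names resolved through
#' [label_vocabulary()]; unknown names are an error, never a new class.
#'
#' @param path file to read.
#' @param delimiter field separator (default `","`).
#' @param has_time_index `NA` (default) detects a time column by name;
#'   `TRUE` forces dropping the first column; `FALSE` keeps all columns.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, delimiter = ",", has_time_index = NA) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (isTRUE(has_time_index)) {
    df <- df[, -1, drop = FALSE]
  } else if (is.na(has_time_index)) {
    drop <- tolower(names(df)) %in% c("time", "time_index", "time.index")
    df <- df[, !drop, drop = FALSE]
  }
  if (ncol(df) < 2) stop_arg("expected at least one feature column plus a label column")
  lab_col <- ncol(df)
  if (tolower(names(df)[lab_col]) != "label") {
    stop_arg("last column must be named 'label', found '", names(df)[lab_col], "'")
  }
  labels_raw <- df[[lab_col]]
  feats <- df[, -lab_col, drop = FALSE]
  for (j in seq_along(feats)) {
    v <- feats[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop_arg(sprintf("non-numeric value '%s' at row %d, column '%s'",
                         v[bad[1]], bad[1], names(feats)[j]))
      }
      feats[[j]] <- vn
    }
  }
  labels <- resolve_labels(labels_raw)
  feature_table(as.matrix(feats), labels, names(feats))
}

# map label names through the vocabulary; pass integers through
resolve_labels <- function(labels_raw) {
  if (length(labels_raw) == 0) return(integer(0))
  if (is.numeric(labels_raw)) return(as.integer(labels_raw))
  vocab <- label_vocabulary()
  idx <- match(trimws(labels_raw), vocab)
  if (anyNA(idx) && length(labels_raw)) {
    bad <- labels_raw[which(is.na(idx))[1]]
    stop_arg("unknown class name: '", bad, "'")
  }
  as.integer(idx - 1L)
}

#' Write a feature table to a delimited file
#'
#' Header plus one row per sample; numeric cells keep 15 significant digits
#' so a write/read round trip is the identity to at least 12 digits.
#'
#' @param table a [feature_table()].
#' @param path destination file.
#' @param delimiter field separator (default `","`).
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$features)
  df$label <- table$labels
  ok <- tryCatch({
    utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_arg("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Stratified 80/20-style train/test split
#'
#' Draws `round(n * test_fraction)` test rows. Under stratification the test
#' total is apportioned across classes by largest remainder over class
#' sizes, so each class's test count differs from `class_count *
#' test_fraction` by less than one row. Membership is seeded and
#' deterministic.
#'
#' @param table a [feature_table()].
#' @param test_fraction proportion in `[0, 1)` held out (default 0.2).
#' @param seed integer seed.
#' @param stratified preserve class proportions (default `TRUE`).
#' @return a `split_result`: list with `train`, `test` (feature tables),
#'   `test_fraction`, `seed`, `stratified`, and the selected `test_idx`.
#' @export
stratified_split <- function(table, test_fraction = 0.2, seed = 0,
                             stratified = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  if (test_fraction < 0 || test_fraction >= 1) {
    stop_arg("test_fraction must lie in [0, 1)")
  }
  n <- ft_nrow(table)
  m <- round(n * test_fraction)
  if (stratified) {
    classes <- sort(unique(table$labels))
    sizes <- vapply(classes, function(cl) sum(table$labels == cl), 0L)
    if (any(sizes == 0L)) stop_arg("every class needs at least one row")
    per_class <- largest_remainder(m, sizes)
    test_idx <- integer(0)
    sub_seeds <- derive_seeds(seed, length(classes))
    for (i in seq_along(classes)) {
      rows <- which(table$labels == classes[i])
      take <- with_seed(sub_seeds[i], sample(rows, per_class[i]))
      test_idx <- c(test_idx, take)
    }
  } else {
    test_idx <- with_seed(seed, sample.int(n, m))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  structure(list(train = ft_subset(table, train_idx),
                 test = ft_subset(table, test_idx),
                 test_fraction = test_fraction,
                 seed = as.integer(seed),
                 stratified = stratified,
                 test_idx = test_idx),
            class = "split_result")
}

#' Fit a per-feature z-score normalizer on training data
#'
#' Means and standard deviations are estimated on the training partition
#' only and then applied unchanged to any partition, the standard
#' leakage-safe protocol. Constant features (sd 0) are centred and left
#' unscaled.
#'
#' @param train a [feature_table()].
#' @return a `normalizer` with `mean` and `sd` per feature.
#' @export
fit_normalizer <- function(train) {
  stopifnot(inherits(train, "feature_table"))
  mu <- colMeans(train$features)
  sd <- apply(train$features, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  structure(list(mean = mu, sd = sd), class = "normalizer")
}

#' Apply a fitted normalizer
#' @param normalizer a [fit_normalizer()] result.
#' @param table a [feature_table()].
#' @return normalized [feature_table()].
#' @export
apply_normalizer <- function(normalizer, table) {
  stopifnot(inherits(normalizer, "normalizer"),
            inherits(table, "feature_table"))
  z <- sweep(sweep(table$features, 2, normalizer$mean), 2, normalizer$sd, "/")
  feature_table(z, table$labels, table$feature_names)
}
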