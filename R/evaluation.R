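# Metric tables, confusion matrices and k-fold cross-validation.
#
# Conventions: per-class precision TP/(TP+FP), recall TP/(TP+FN), F1 their
# harmonic mean; zero denominators yield 0 with a warning. Averages come in
# two flavours, macro (unweighted over classes) and weighted (by support).
# Averages are computed from full-precision per-class values; rounding
# (half away from zero, two decimals) happens only at display time.

#' Confusion matrix
#'
#' Entry `(i, j)` counts rows whose true class is `i - 1` and predicted
#' class `j - 1`.
#'
#' @param y_true,y_pred 0-based integer labels of equal length.
#' @param K class count; labels must lie in `0..K-1`.
#' @return `K x K` integer matrix named by class index.
#' @export
confusion_matrix <- function(y_true, y_pred, K = max(y_true, y_pred) + 1L) {
  if (length(y_true) != length(y_pred)) {
    stop_arg("y_true and y_pred must have equal length")
  }
  if (length(y_true) &&
      (min(y_true, y_pred) < 0 || max(y_true, y_pred) >= K)) {
    stop_arg("labels out of range 0..", K - 1)
  }
  idx <- as.integer(y_true) * K + as.integer(y_pred) + 1L
  cm <- matrix(tabulate(idx, nbins = K * K), K, K, byrow = TRUE,
               dimnames = list(true = seq_len(K) - 1L,
                               pred = seq_len(K) - 1L))
  cm
}

#' Per-class classification report
#'
#' Accuracy, per-class precision/recall/F1/support, macro and
#' support-weighted averages, and the confusion matrix.
#'
#' @param y_true,y_pred 0-based labels of equal length.
#' @param K class count (default inferred).
#' @param label_names optional class names; default [label_vocabulary()]
#'   when `K == 8`, else the class index.
#' @return an `eval_report` list: `accuracy`, `per_class` data frame,
#'   `macro` and `weighted` (precision/recall/f1), `confusion`,
#'   `label_names`, `n`.
#' @export
classification_report <- function(y_true, y_pred,
                                  K = max(y_true, y_pred) + 1L,
                                  label_names = NULL) {
  cm <- confusion_matrix(y_true, y_pred, K)
  support <- rowSums(cm)
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warning(what, " undefined for class(es) ",
              paste(which(den == 0) - 1L, collapse = ", "),
              "; reported as 0", call. = FALSE)
    }
    out
  }
  precision <- safe_div(tp, pred_tot, "precision")
  recall <- safe_div(tp, support, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  if (is.null(label_names)) {
    label_names <- if (K == 8) label_vocabulary() else
      paste0("class_", seq_len(K) - 1L)
  }
  n <- length(y_true)
  w <- if (n > 0) support / n else rep(0, K)
  structure(list(
    accuracy = if (n > 0) sum(tp) / n else NA_real_,
    per_class = data.frame(class = seq_len(K) - 1L, name = label_names,
                           precision = precision, recall = recall, f1 = f1,
                           support = as.integer(support),
                           row.names = NULL),
    macro = list(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
    weighted = list(precision = sum(w * precision),
                    recall = sum(w * recall),
                    f1 = sum(w * f1)),
    confusion = cm,
    label_names = label_names,
    n = n), class = "eval_report")
}

#' Support-weighted average of a per-class metric
#'
#' `sum(values * support) / sum(support)` — the averaging used for the
#' "Average" row of a metric table over imbalanced classes.
#'
#' @param values per-class metric values.
#' @param support per-class true-instance counts.
#' @return the weighted mean.
#' @export
weighted_metric <- function(values, support) {
  stopifnot(length(values) == length(support), sum(support) > 0)
  sum(values * support) / sum(support)
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat(sprintf("accuracy: %.2f  (n = %d)\n", round_half_up(x$accuracy, digits),
              x$n))
  df <- x$per_class
  df$precision <- round_half_up(df$precision, digits)
  df$recall <- round_half_up(df$recall, digits)
  df$f1 <- round_half_up(df$f1, digits)
  print(df, row.names = FALSE)
  cat(sprintf("macro     avg: P=%.2f R=%.2f F1=%.2f\n",
              round_half_up(x$macro$precision, digits),
              round_half_up(x$macro$recall, digits),
              round_half_up(x$macro$f1, digits)))
  cat(sprintf("weighted  avg: P=%.2f R=%.2f F1=%.2f\n",
              round_half_up(x$weighted$precision, digits),
              round_half_up(x$weighted$recall, digits),
              round_half_up(x$weighted$f1, digits)))
  invisible(x)
}

#' Serialize a report to a delimited metrics table
#'
#' Columns: Technique, Accuracy, Target exercise, Precision, Recall, F1,
#' Support; one row per class plus the Average row (weighted averages).
#'
#' @param report an [classification_report()] result.
#' @param technique label for the Technique column.
#' @param path destination file; `NULL` returns the data frame.
#' @param digits display rounding (half away from zero).
#' @return the data frame, invisibly when written.
#' @export
report_to_table <- function(report, technique = "model", path = NULL,
                            digits = 2) {
  pc <- report$per_class
  df <- data.frame(
    Technique = technique,
    Accuracy = round_half_up(report$accuracy, digits),
    `Target exercise` = c(as.character(pc$name), "Average"),
    Precision = round_half_up(c(pc$precision, report$weighted$precision), digits),
    Recall = round_half_up(c(pc$recall, report$weighted$recall), digits),
    F1 = round_half_up(c(pc$f1, report$weighted$f1), digits),
    Support = c(pc$support, sum(pc$support)),
    check.names = FALSE)
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(df)
}

#' Stratified k-fold cross-validation
#'
#' Splits the table into `k` stratified folds. Per fold, an optional
#' normalizer and (when `use_rfl`) the transfer-feature extractors are
#' fitted on the fold's training part only and applied to both parts, so
#' nothing crosses the fold boundary; the classifier is then trained and
#' scored on the held-out fold.
#'
#' @param spec a [classifier_spec()].
#' @param table a [feature_table()]; every class needs at least `k` rows.
#' @param k folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param use_rfl compute transfer features per fold (default `FALSE`).
#' @param rfl_cfg an [rfl_config()] when `use_rfl`.
#' @param normalize z-score per fold (default `TRUE`).
#' @return a `cv_report`: `k`, `fold_accuracy`, `mean`, `sd` (sample,
#'   n-1), `seed`.
#' @export
kfold_cv <- function(spec, table, k = 10, seed = 0, use_rfl = FALSE,
                     rfl_cfg = rfl_config(), normalize = TRUE) {
  stopifnot(k >= 2)
  folds <- stratified_folds(table$labels, k, seed = seed)
  kk <- max(table$labels) + 1L
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- ft_subset(table, which(folds != f))
    te <- ft_subset(table, which(folds == f))
    if (normalize) {
      nz <- fit_normalizer(tr)
      tr <- apply_normalizer(nz, tr)
      te <- apply_normalizer(nz, te)
    }
    if (use_rfl) {
      tf <- rfl_transform(tr, config = rfl_cfg, mode = "in_sample",
                          class_count = kk)
      tr_x <- as_feature_table(tf, tr$labels)
      te_x <- feature_table(rfl_apply(tf, te$features), te$labels)
    } else {
      tr_x <- tr
      te_x <- te
    }
    model <- train_classifier(spec, tr_x, class_count = kk)
    acc[f] <- mean(predict(model, te_x) == te$labels)
  }
  structure(list(k = as.integer(k), fold_accuracy = acc,
                 mean = mean(acc), sd = stats::sd(acc),
                 seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV accuracy: %.4f (sd %.4f)\n", x$k, x$mean, x$sd))
  invisible(x)
}

# --- runtime logging -------------------------------------------------------

the_runtime_log <- new.env(parent = emptyenv())
the_runtime_log$records <- list()
the_runtime_log$enabled <- TRUE

#' Record a stage timing
#'
#' Appends a structured timing record. Informational only; timings are
#' hardware-dependent and never enter any metric.
#'
#' @param stage stage name (e.g. `"train"`, `"transform"`, `"evaluate"`).
#' @param seconds elapsed wall time.
#' @return the record, invisibly (`NULL` when logging is disabled).
#' @export
runtime_log <- function(stage, seconds) {
  if (!the_runtime_log$enabled) return(invisible(NULL))
  rec <- list(stage = stage, seconds = as.numeric(seconds),
              at = Sys.time())
  the_runtime_log$records[[length(the_runtime_log$records) + 1L]] <- rec
  invisible(rec)
}

#' Enable or disable runtime logging
#' @param enabled logical.
#' @return previous state, invisibly.
#' @export
runtime_log_enable <- function(enabled = TRUE) {
  prev <- the_runtime_log$enabled
  the_runtime_log$enabled <- isTRUE(enabled)
  invisible(prev)
}

#' Retrieve (and optionally clear) runtime records
#' @param clear drop stored records after returning them.
#' @return list of records in insertion order.
#' @export
runtime_log_records <- function(clear = FALSE) {
  out <- the_runtime_log$records
  if (clear) the_runtime_log$records <- list()
  out
}
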