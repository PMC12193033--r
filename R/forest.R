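# Random-forest probability extractor.
#
# A bootstrap-aggregated ensemble of CART trees (rpart) with
# entropy ("information") splitting, a depth cap, and per-tree random
# feature subspaces. The ensemble keeps every tree accessible because the
# quantity of interest is not the vote but the averaged per-tree class
# distribution P(c|x) = (1/N) * sum_i P_i(c|x), which becomes the
# probabilistic half of the transfer-feature matrix.
#
# Feature subsampling is per tree (random subspace method) rather than per
# node; rpart exposes no per-node hook, and at 9 input channels the
# difference is immaterial for the ensemble's purpose here.

#' Fit a random-forest probability extractor
#'
#' Reference defaults: 10 trees, depth cap 10, entropy splitting, seed 0.
#'
#' @param train a [feature_table()] with at least two classes.
#' @param n_trees number of trees `N` (default 10).
#' @param max_depth depth cap per tree (default 10).
#' @param criterion `"entropy"` (information gain) or `"gini"`.
#' @param mtry features sampled per tree; default `floor(sqrt(p))`.
#' @param seed integer seed for bootstraps and feature subsets (default 0).
#' @param class_count number of classes `K`; default inferred from labels.
#' @return an `rf_extractor`: list of fitted trees plus metadata.
#' @export
fit_rf_extractor <- function(train, n_trees = 10, max_depth = 10,
                             criterion = c("entropy", "gini"),
                             mtry = NULL, seed = 0, class_count = NULL) {
  stopifnot(inherits(train, "feature_table"), n_trees >= 1)
  criterion <- match.arg(criterion)
  n <- ft_nrow(train)
  if (n == 0) stop_arg("train must be nonempty")
  k <- if (is.null(class_count)) max(train$labels) + 1L else as.integer(class_count)
  if (length(unique(train$labels)) < 2) {
    stop_arg("training data holds a single class; need >= 2")
  }
  p <- ncol(train$features)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  split_name <- if (criterion == "entropy") "information" else "gini"
  tree_seeds <- derive_seeds(seed, 2L * n_trees)

  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    boot <- with_seed(tree_seeds[2L * i - 1L], sample.int(n, n, replace = TRUE))
    feats <- sort(with_seed(tree_seeds[2L * i], sample.int(p, mtry)))
    yb <- train$labels[boot]
    if (length(unique(yb)) < 2) {
      # degenerate bootstrap: constant tree predicting its single class
      prob <- numeric(k); prob[yb[1] + 1L] <- 1
      trees[[i]] <- new_stub_tree(prob)
      next
    }
    df <- as.data.frame(train$features[boot, feats, drop = FALSE])
    names(df) <- paste0("V", feats)
    df$.y <- factor(yb)
    fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                        parms = list(split = split_name),
                        control = rpart::rpart.control(
                          maxdepth = max_depth, cp = 0, minsplit = 2,
                          minbucket = 1, xval = 0))
    trees[[i]] <- structure(list(kind = "rpart", fit = fit, feats = feats,
                                 levels = as.integer(levels(df$.y))),
                            class = "rfl_tree")
  }
  structure(list(trees = trees, n_trees = as.integer(n_trees),
                 class_count = k, max_depth = max_depth,
                 criterion = criterion, mtry = as.integer(mtry),
                 seed = as.integer(seed),
                 feature_names = train$feature_names),
            class = "rf_extractor")
}

# a tree with a fixed class distribution, used for degenerate bootstraps
# and as an injectable stub in tests of the averaging formula
new_stub_tree <- function(prob) {
  stopifnot(all(prob >= 0), abs(sum(prob) - 1) < 1e-9)
  structure(list(kind = "constant", prob = as.numeric(prob)),
            class = "rfl_tree")
}

# build an extractor directly from fixed per-tree distributions
rf_extractor_from_stubs <- function(probs) {
  k <- length(probs[[1]])
  structure(list(trees = lapply(probs, new_stub_tree),
                 n_trees = length(probs), class_count = k,
                 max_depth = NA, criterion = "entropy", mtry = NA,
                 seed = NA_integer_, feature_names = NULL),
            class = "rf_extractor")
}

# per-tree class distribution over K classes for every row of X
tree_class_prob <- function(tree, X, k) {
  if (tree$kind == "constant") {
    return(matrix(tree$prob, nrow = nrow(X), ncol = k, byrow = TRUE))
  }
  df <- as.data.frame(X[, tree$feats, drop = FALSE])
  names(df) <- paste0("V", tree$feats)
  raw <- stats::predict(tree$fit, df, type = "prob")
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = nrow(X))
  out <- matrix(0, nrow = nrow(X), ncol = k)
  out[, tree$levels + 1L] <- raw
  out
}

#' Random-forest class-probability features
#'
#' Row `r`, class `c` of the output is the forest-averaged probability
#' `(1/N) * sum_i P_i(c | X_r)`; every row sums to 1.
#'
#' @param extractor an [fit_rf_extractor()] result.
#' @param X a [feature_table()] or numeric matrix with matching columns.
#' @return an `n x K` probability matrix with columns `rf_p0..rf_p{K-1}`.
#' @export
rf_probability_features <- function(extractor, X) {
  stopifnot(inherits(extractor, "rf_extractor"))
  M <- if (inherits(X, "feature_table")) X$features else as.matrix(X)
  if (!is.null(extractor$feature_names) &&
      ncol(M) != length(extractor$feature_names)) {
    stop_arg("feature dimension mismatch: extractor saw ",
             length(extractor$feature_names), " columns, input has ", ncol(M))
  }
  k <- extractor$class_count
  acc <- matrix(0, nrow = nrow(M), ncol = k)
  for (tree in extractor$trees) acc <- acc + tree_class_prob(tree, M, k)
  probs <- acc / extractor$n_trees
  colnames(probs) <- paste0("rf_p", seq_len(k) - 1L)
  probs
}
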