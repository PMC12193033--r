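# Downstream classifiers with reference hyperparameters.
#
# Reference defaults (the tuned settings the package reproduces):
#   RF : n_trees = 10, max_depth = 10, criterion = entropy, seed = 0
#   DT : unbounded leaves, zero impurity-decrease floor (cp = 0)
#   LR : multinomial softmax, L2 at C = 1.0, 200 iterations, seed = 0
#   GNB: empirical priors, var_smoothing = 1e-9
#
# Gaussian naive Bayes is estimated natively (class priors, per-class
# per-feature means and maximum-likelihood variances, log-space scoring) so
# the density and posterior formulas are directly testable. The logistic
# probability formula is likewise native. Tree/forest/softmax fitting
# delegates to rpart and nnet.

#' Specify a downstream classifier
#'
#' @param kind one of `"rf"`, `"dt"`, `"lr"`, `"gnb"`, or the trivial
#'   baseline `"majority"`.
#' @param seed integer seed (used by `rf` and `lr`).
#' @param ... hyperparameter overrides; unknown names are rejected.
#'   `rf`: `n_trees`, `max_depth`, `criterion`, `mtry`.
#'   `dt`: `max_depth`, `cp`, `criterion`.
#'   `lr`: `C`, `max_iter`.
#'   `gnb`: `var_smoothing`, `priors`.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("rf", "dt", "lr", "gnb", "majority"),
                            seed = 0, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    rf = list(n_trees = 10, max_depth = 10, criterion = "entropy",
              mtry = NULL),
    dt = list(max_depth = 30, cp = 0, criterion = "gini"),
    lr = list(C = 1.0, max_iter = 200),
    gnb = list(var_smoothing = 1e-9, priors = NULL),
    majority = list())
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown)) {
    stop_arg("unknown hyperparameter(s) for ", kind, ": ",
             paste(unknown, collapse = ", "))
  }
  defaults[names(extra)] <- extra
  structure(list(kind = kind, hyperparameters = defaults,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a downstream classifier
#'
#' @param spec a [classifier_spec()].
#' @param table a [feature_table()] with at least two classes (the
#'   `majority` baseline accepts one).
#' @param class_count classes K; default inferred from labels.
#' @return a `fitted_model` carrying the spec and backend fit.
#' @export
train_classifier <- function(spec, table, class_count = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(table, "feature_table"))
  if (ft_nrow(table) == 0) stop_arg("training table is empty")
  k <- if (is.null(class_count)) max(table$labels) + 1L else as.integer(class_count)
  if (spec$kind != "majority" && length(unique(table$labels)) < 2) {
    stop_arg("training data holds a single class; need >= 2")
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$kind,
    rf = fit_rf_extractor(table, n_trees = hp$n_trees,
                          max_depth = hp$max_depth,
                          criterion = hp$criterion, mtry = hp$mtry,
                          seed = spec$seed, class_count = k),
    dt = {
      df <- as.data.frame(table$features)
      names(df) <- paste0("V", seq_len(ncol(df)))
      df$.y <- factor(table$labels, levels = seq_len(k) - 1L)
      df$.y <- droplevels(df$.y)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = if (hp$criterion == "entropy")
                     "information" else "gini"),
                   control = rpart::rpart.control(
                     maxdepth = hp$max_depth, cp = hp$cp, minsplit = 2,
                     minbucket = 1, xval = 0))
    },
    lr = {
      df <- as.data.frame(table$features)
      names(df) <- paste0("V", seq_len(ncol(df)))
      df$.y <- droplevels(factor(table$labels, levels = seq_len(k) - 1L))
      with_seed(spec$seed,
                nnet::multinom(.y ~ ., data = df,
                               decay = 1 / (2 * hp$C),
                               maxit = hp$max_iter, trace = FALSE,
                               MaxNWts = 100000))
    },
    gnb = fit_gnb(table$features, table$labels, k,
                  var_smoothing = hp$var_smoothing, priors = hp$priors),
    majority = {
      tab <- tabulate(table$labels + 1L, nbins = k)
      list(class = which.max(tab) - 1L)  # which.max ties -> lowest index
    })
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 class_count = k,
                 levels_seen = sort(unique(table$labels)),
                 n_features = ncol(table$features)),
            class = "fitted_model")
}

#' Gaussian naive Bayes parameter estimation
#'
#' Per class: empirical prior (unless overridden), per-feature mean and
#' maximum-likelihood variance. Smoothing `var_smoothing * max_f Var(x_f)`
#' (largest overall feature variance) is added to every variance so none is
#' degenerate.
#'
#' @param X numeric matrix.
#' @param y 0-based labels.
#' @param class_count classes K.
#' @param var_smoothing relative smoothing (default 1e-9).
#' @param priors optional length-K prior overriding the empirical one.
#' @return a `gnb_params` list: `priors`, `mu` (K x p), `var` (K x p,
#'   smoothed), `var_raw`, `epsilon`.
#' @export
fit_gnb <- function(X, y, class_count = max(y) + 1L, var_smoothing = 1e-9,
                    priors = NULL) {
  X <- as.matrix(X)
  k <- as.integer(class_count)
  p <- ncol(X)
  mu <- matrix(NA_real_, k, p)
  v <- matrix(NA_real_, k, p)
  counts <- numeric(k)
  for (cl in seq_len(k) - 1L) {
    rows <- which(y == cl)
    counts[cl + 1L] <- length(rows)
    if (!length(rows)) next
    Xi <- X[rows, , drop = FALSE]
    mu[cl + 1L, ] <- colMeans(Xi)
    v[cl + 1L, ] <- colMeans(Xi^2) - colMeans(Xi)^2  # ML variance
  }
  if (is.null(priors)) {
    priors <- counts / sum(counts)
  } else {
    stopifnot(length(priors) == k, all(priors >= 0),
              abs(sum(priors) - 1) < 1e-9)
  }
  total_var <- colMeans(X^2) - colMeans(X)^2
  eps <- var_smoothing * max(total_var)
  structure(list(priors = priors, mu = mu, var = v + eps, var_raw = v,
                 epsilon = eps, class_count = k),
            class = "gnb_params")
}

#' Gaussian feature likelihood
#'
#' The class-conditional density of one feature value under the naive-Bayes
#' Gaussian model: `1/sqrt(2*pi*var) * exp(-(x - mu)^2 / (2*var))`.
#'
#' @param x_i feature value(s).
#' @param mu class-conditional mean.
#' @param var class-conditional variance (> 0).
#' @return density value(s).
#' @export
gnb_feature_likelihood <- function(x_i, mu, var) {
  if (any(var <= 0)) stop_arg("var must be > 0")
  1 / sqrt(2 * pi * var) * exp(-(x_i - mu)^2 / (2 * var))
}

# log posterior P(C | x) for every row, computed in log space
gnb_log_posterior <- function(params, X) {
  X <- as.matrix(X)
  k <- params$class_count
  lp <- matrix(-Inf, nrow(X), k)
  for (cl in seq_len(k)) {
    if (params$priors[cl] == 0 || anyNA(params$mu[cl, ])) next
    mu <- params$mu[cl, ]; v <- params$var[cl, ]
    ll <- -0.5 * sweep(sweep(X, 2, mu)^2, 2, v, "/") -
      matrix(0.5 * log(2 * pi * v), nrow(X), ncol(X), byrow = TRUE)
    lp[, cl] <- log(params$priors[cl]) + rowSums(ll)
  }
  lp
}

#' Binary logistic probability
#'
#' `P(y = 1 | x) = 1 / (1 + exp(-(beta0 + sum(beta * x))))`; the
#' complementary class has probability one minus this value.
#'
#' @param x feature vector (may be empty for an intercept-only model).
#' @param beta0 intercept.
#' @param beta coefficient vector, same length as `x`.
#' @return probability of class 1.
#' @export
lr_probability <- function(x, beta0, beta = numeric(0)) {
  if (length(beta) != length(x)) {
    stop_arg("beta and x must have the same length")
  }
  1 / (1 + exp(-(beta0 + sum(beta * x))))
}

#' Class-probability predictions
#'
#' @param model a [train_classifier()] result.
#' @param X a [feature_table()] or numeric matrix.
#' @return `n x K` matrix; every row sums to 1.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "fitted_model"))
  M <- if (inherits(X, "feature_table")) X$features else as.matrix(X)
  if (ncol(M) != model$n_features) {
    stop_arg("input has ", ncol(M), " columns; model expects ",
             model$n_features)
  }
  k <- model$class_count
  probs <- switch(model$kind,
    rf = rf_probability_features(model$fit, M),
    dt = {
      df <- as.data.frame(M)
      names(df) <- paste0("V", seq_len(ncol(df)))
      raw <- stats::predict(model$fit, df, type = "prob")
      if (is.null(dim(raw))) raw <- matrix(raw, nrow = nrow(M))
      out <- matrix(0, nrow(M), k)
      out[, as.integer(colnames(raw)) + 1L] <- raw
      out
    },
    lr = {
      df <- as.data.frame(M)
      names(df) <- paste0("V", seq_len(ncol(df)))
      raw <- stats::predict(model$fit, df, type = "probs")
      if (is.null(dim(raw))) {
        # binary case: multinom returns P(second level)
        raw <- cbind(1 - raw, raw)
      }
      out <- matrix(0, nrow(M), k)
      out[, model$levels_seen + 1L] <- raw
      out
    },
    gnb = {
      lp <- gnb_log_posterior(model$fit, M)
      mx <- apply(lp, 1, max)
      e <- exp(lp - mx)
      e / rowSums(e)
    },
    majority = {
      out <- matrix(0, nrow(M), k)
      out[, model$fit$class + 1L] <- 1
      out
    })
  colnames(probs) <- paste0("p", seq_len(k) - 1L)
  probs
}

#' Predicted class labels
#'
#' Argmax of [predict_proba()]; exact probability ties break to the lowest
#' class index.
#'
#' @param object a [train_classifier()] result.
#' @param X a [feature_table()] or numeric matrix.
#' @param ... unused.
#' @return integer vector of 0-based labels.
#' @export
predict.fitted_model <- function(object, X, ...) {
  argmax_class(predict_proba(object, X))
}
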