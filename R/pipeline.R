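# End-to-end workflow: simulate/read -> split -> normalize -> transfer
# features -> train -> evaluate, driven by a validated YAML config. This is
# the layer the command-line script (inst/cli/rflhar) wraps.

default_run_config <- function() {
  list(
    input = NULL,            # path to a delimited table; NULL -> simulate
    out_dir = ".",
    seed = 0L,
    log_level = "info",
    sim = list(n_rows = 4000L, template_gap = 1, noise_sd = 0.3,
               subject_offset_sd = 0.2, n_subjects = 5L, sample_rate = 25,
               class_proportions = NULL),
    split = list(test_fraction = 0.2, stratified = TRUE),
    normalize = TRUE,
    rfl = list(enabled = TRUE, mode = "in_sample", oof_folds = 5L,
               hidden_size = 32L, window_len = 1L, epochs = 10L,
               n_trees = 10L, max_depth = 10L, criterion = "entropy"),
    classifier = list(kind = "rf"),
    evaluation = list(kfold = 0L)
  )
}

merge_validated <- function(base, user, path = "config") {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop_arg("unknown key(s) under ", path, ": ",
             paste(unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_validated(base[[nm]], user[[nm]],
                                    paste0(path, "$", nm))
    } else {
      base[nm] <- user[nm]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), merges it over the defaults and
#' rejects unknown keys. A single global `seed` pins simulation, split,
#' extractor and classifier sub-seeds.
#'
#' @param source path to a YAML file, a list, or `NULL` for defaults.
#' @return a validated `run_config` list.
#' @export
run_config <- function(source = NULL) {
  user <- if (is.character(source)) yaml::read_yaml(source) else source
  cfg <- merge_validated(default_run_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg$sim$n_rows <- as.integer(cfg$sim$n_rows)
  structure(cfg, class = "run_config")
}

# hash of the scientific configuration; output location excluded so two
# runs of the same analysis share a hash wherever they write
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

sim_spec_from_config <- function(cfg, seed) {
  s <- cfg$sim
  templates <- default_templates(gap = s$template_gap)
  props <- s$class_proportions
  if (is.null(props)) props <- benchmark_class_proportions(length(templates))
  sim_spec(templates = templates, class_proportions = props,
           n_subjects = s$n_subjects, subject_offset_sd = s$subject_offset_sd,
           noise_sd = s$noise_sd, sample_rate = s$sample_rate, seed = seed)
}

rfl_config_from_config <- function(cfg, seeds) {
  r <- cfg$rfl
  rfl_config(n_trees = r$n_trees, max_depth = r$max_depth,
             criterion = r$criterion, rf_seed = seeds[1],
             hidden_size = r$hidden_size, window_len = r$window_len,
             epochs = r$epochs, lstm_seed = seeds[2])
}

#' Simulate a dataset to a delimited file
#'
#' Writes the feature table plus a YAML sidecar (`<file>.meta.yaml`)
#' recording the generator settings, per-class counts, the seed and the
#' config hash.
#'
#' @param cfg a [run_config()].
#' @param path output table path.
#' @return invisibly, a list with `path`, `meta_path` and the class counts.
#' @export
simulate_to_file <- function(cfg, path) {
  cfg <- run_config(cfg)
  seeds <- derive_seeds(cfg$seed, 2)
  spec <- sim_spec_from_config(cfg, seeds[1])
  tab <- generate_dataset(spec, cfg$sim$n_rows, seed = seeds[2])
  write_feature_table(tab, path)
  counts <- as.integer(tabulate(tab$labels + 1L, nbins = length(spec$templates)))
  meta <- list(n_rows = ft_nrow(tab), class_counts = counts,
               seed = cfg$seed, sim = cfg$sim, config_hash = config_hash(cfg))
  meta_path <- paste0(path, ".meta.yaml")
  yaml::write_yaml(meta, meta_path)
  invisible(list(path = path, meta_path = meta_path, class_counts = counts))
}

#' Run the full classification workflow
#'
#' Simulates (or reads) a table, splits it, optionally normalizes and
#' computes transfer features, trains the configured classifier, evaluates
#' on the held-out partition and optionally runs k-fold cross-validation.
#' Result files (`report.csv`, `confusion.csv`, `summary.json`) carry the
#' config hash for provenance.
#'
#' @param cfg a [run_config()] (list, path, or `NULL` for defaults).
#' @param write_files write result files under `cfg$out_dir` (default
#'   `TRUE`).
#' @return a list with `report` ([classification_report()]), `cv`
#'   (`cv_report` or `NULL`), `model`, `split`, and `config_hash`.
#' @export
run_pipeline <- function(cfg = NULL, write_files = TRUE) {
  cfg <- run_config(cfg)
  seeds <- derive_seeds(cfg$seed, 6)
  t0 <- proc.time()["elapsed"]

  tab <- if (is.null(cfg$input)) {
    spec <- sim_spec_from_config(cfg, seeds[1])
    generate_dataset(spec, cfg$sim$n_rows, seed = seeds[2])
  } else {
    read_feature_table(cfg$input)
  }
  k <- max(tab$labels) + 1L

  sp <- stratified_split(tab, cfg$split$test_fraction, seed = seeds[3],
                         stratified = cfg$split$stratified)
  train <- sp$train; test <- sp$test
  if (isTRUE(cfg$normalize)) {
    nz <- fit_normalizer(train)
    train <- apply_normalizer(nz, train)
    test <- apply_normalizer(nz, test)
  }
  runtime_log("prepare", proc.time()["elapsed"] - t0)

  t0 <- proc.time()["elapsed"]
  if (isTRUE(cfg$rfl$enabled)) {
    rcfg <- rfl_config_from_config(cfg, seeds[4:5])
    tf_train <- rfl_transform(train, config = rcfg, mode = cfg$rfl$mode,
                              oof_folds = cfg$rfl$oof_folds, class_count = k)
    if (cfg$rfl$mode == "out_of_fold") {
      # held-out features come from extractors refitted on all of train
      tf_full <- rfl_transform(train, config = rcfg, mode = "in_sample",
                               class_count = k)
      test_x <- feature_table(rfl_apply(tf_full, test$features), test$labels)
    } else {
      test_x <- feature_table(rfl_apply(tf_train, test$features), test$labels)
    }
    train_x <- as_feature_table(tf_train, train$labels)
  } else {
    train_x <- train
    test_x <- test
  }
  runtime_log("transform", proc.time()["elapsed"] - t0)

  t0 <- proc.time()["elapsed"]
  spec_cl <- classifier_spec(cfg$classifier$kind, seed = seeds[6])
  model <- train_classifier(spec_cl, train_x, class_count = k)
  runtime_log("train", proc.time()["elapsed"] - t0)

  t0 <- proc.time()["elapsed"]
  report <- classification_report(test_x$labels, predict(model, test_x), k)
  cv <- NULL
  if (cfg$evaluation$kfold >= 2) {
    cv <- kfold_cv(spec_cl, tab, k = cfg$evaluation$kfold, seed = seeds[3],
                   use_rfl = isTRUE(cfg$rfl$enabled),
                   rfl_cfg = if (isTRUE(cfg$rfl$enabled))
                     rfl_config_from_config(cfg, seeds[4:5]) else rfl_config(),
                   normalize = isTRUE(cfg$normalize))
  }
  runtime_log("evaluate", proc.time()["elapsed"] - t0)

  hash <- config_hash(cfg)
  if (write_files) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    report_to_table(report, technique = toupper(cfg$classifier$kind),
                    path = file.path(cfg$out_dir, "report.csv"))
    utils::write.table(report$confusion,
                       file.path(cfg$out_dir, "confusion.csv"),
                       sep = ",", col.names = NA)
    summary <- list(config_hash = hash, seed = cfg$seed,
                    classifier = cfg$classifier$kind,
                    rfl_mode = if (isTRUE(cfg$rfl$enabled)) cfg$rfl$mode else "disabled",
                    accuracy = report$accuracy,
                    weighted_precision = report$weighted$precision,
                    weighted_recall = report$weighted$recall,
                    weighted_f1 = report$weighted$f1,
                    cv_mean = if (!is.null(cv)) cv$mean else NULL,
                    cv_sd = if (!is.null(cv)) cv$sd else NULL)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(report = report, cv = cv, model = model, split = sp,
       config_hash = hash)
}
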