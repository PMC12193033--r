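# Shared fixtures: small simulation specs and toy tables built in code.

# reference well-separated spec (default templates, default noise)
ref_spec <- function(...) sim_spec(...)

# identical templates across classes: the chance-level regime
flat_spec <- function(noise_sd = 0.5) {
  sim_spec(templates = default_templates(gap = 0), noise_sd = noise_sd,
           subject_offset_sd = 0)
}

small_table <- function(n = 400, seed = 1, spec = ref_spec()) {
  generate_dataset(spec, n, seed = seed)
}

# two well-separated 2-D gaussian blobs, classes 0/1
toy_blobs <- function(n_per = 20, seed = 1, sep = 6) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
             matrix(rnorm(n_per * 2, mean = sep), ncol = 2))
  feature_table(X, rep(0:1, each = n_per), c("f1", "f2"))
}

# zeroed LSTM parameter set for fixed-point checks
zero_lstm <- function(hidden = 3, d = 2) {
  ex <- lstm_init(input_dim = d, hidden_size = hidden, class_count = 2,
                  seed = 0)
  ex$params[] <- lapply(ex$params, function(p) p * 0)
  ex
}
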