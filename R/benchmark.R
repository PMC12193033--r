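# Published benchmark metric cells for the 8-exercise wearable-sensor
# dataset, shipped as a plain-text fixture. The per-class precision and
# support cells are inputs for validating the support-weighted averaging
# convention: recomputing an Average cell from its per-class row must
# reproduce the published two-decimal value.

#' Per-class precision/support cells of the benchmark evaluations
#'
#' Published per-class precision and support values for five techniques on
#' the original 9 sensor features and for the random forest on hybrid
#' transfer features, over the benchmark's 55,325-row test partition.
#'
#' @return data frame with columns `technique`, `feature_set`, `class`,
#'   `precision`, `support`.
#' @export
benchmark_precision_cells <- function() {
  path <- system.file("extdata", "benchmark_precision_cells.csv",
                      package = "rflhar", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
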