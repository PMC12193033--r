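# Internal helpers shared across modules.

#' Run code under a temporary RNG seed
#'
#' Evaluates `expr` with the RNG seeded to `seed`, then restores the caller's
#' RNG state so library calls never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of sub-seeds from one master seed; keeps every consumer of
# randomness (simulation, split, extractors, classifier) on its own stream
# while a single integer pins the whole run. Values stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Largest-remainder apportionment
#'
#' Splits an integer total across categories in proportion to `weights`,
#' guaranteeing the parts sum exactly to `total`. Quotas are floored and the
#' leftover units go to the categories with the largest fractional parts
#' (ties broken by lower index, so the result is deterministic).
#'
#' @param total nonnegative integer to apportion.
#' @param weights nonnegative weights (any positive sum).
#' @return integer vector of counts summing to `total`.
#' @examples
#' largest_remainder(10, c(1, 1, 1))
#' @export
largest_remainder <- function(total, weights) {
  stopifnot(length(total) == 1L, total >= 0, all(weights >= 0))
  if (sum(weights) <= 0) stop("weights must have a positive sum")
  quota <- total * weights / sum(weights)
  counts <- floor(quota)
  left <- as.integer(round(total - sum(counts)))
  if (left > 0) {
    frac <- quota - counts
    take <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Round half away from zero
#'
#' Display rounding used in metric tables: 0.005 at two decimals becomes
#' 0.01, unlike base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# argmax over probability rows with ties broken by the lowest class index;
# returns 0-based class labels.
argmax_class <- function(prob) {
  max.col(prob, ties.method = "first") - 1L
}

stop_arg <- function(...) stop(..., call. = FALSE)
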