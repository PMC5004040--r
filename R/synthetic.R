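# Synthetic experiment records drawn from a known quadratic surface, so
# parameter recovery, stepwise selection power and GA-vs-oracle behaviour
# are all testable against ground truth.

#' Simulate experiment records from a known surface
#'
#' Samples culture conditions uniformly inside the factor box (or as
#' one-factor-at-a-time sweeps mimicking the real design) and draws the
#' response as surface value plus additive Gaussian noise. With
#' `noise_sd = 0` every yield equals the surface value exactly; identical
#' seeds reproduce identical records.
#'
#' @param model True surface: an `rsm_fit` or [printed_yield_model()].
#' @param n Number of records.
#' @param bounds Sampling box, a [factor_bounds()].
#' @param noise_sd Response-scale Gaussian noise standard deviation (>= 0).
#' @param design `"uniform"` (default) or `"sweep"`; the sweep design cycles
#'   one factor at a time over an equispaced grid from the box midpoint.
#' @param seed Optional RNG seed.
#' @return `experiment_records` data frame with `n` rows; negative draws are
#'   possible for noisy low-yield surfaces and are kept (they are data, not
#'   measurements to censor).
#' @examples
#' recs <- simulate_surface(printed_yield_model(), n = 20, noise_sd = 0,
#'                          seed = 1)
#' all.equal(recs$yield, predict(printed_yield_model(), recs))
#' @export
simulate_surface <- function(model, n, bounds = factor_bounds(),
                             noise_sd = 25, design = c("uniform", "sweep"),
                             seed = NULL) {
  stopifnot(n >= 1, noise_sd >= 0, inherits(bounds, "factor_bounds"))
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(bounds)
  if (design == "uniform") {
    m <- sapply(seq_len(p), function(k)
      stats::runif(n, bounds$lo[k], bounds$hi[k]))
    m <- matrix(m, nrow = n)
  } else {
    mid <- (bounds$lo + bounds$hi) / 2
    m <- matrix(mid, n, p, byrow = TRUE)
    fct <- rep(seq_len(p), length.out = n)
    for (i in seq_len(n)) {
      k <- fct[i]
      pos <- (sum(fct[seq_len(i)] == k) - 1) %% 10
      m[i, k] <- bounds$lo[k] + pos / 9 * (bounds$hi[k] - bounds$lo[k])
    }
  }
  conds <- as.data.frame(m)
  names(conds) <- bounds$factor
  mu <- predict(model, conds)
  conds$yield <- mu + stats::rnorm(n, 0, noise_sd)
  class(conds) <- c("experiment_records", "data.frame")
  conds
}

#' One-factor-at-a-time condition sweep
#'
#' Replicates a base condition with one chosen factor swept over given
#' values — the design shape of the real experiments (e.g. a pH sweep at
#' fixed inoculum, volume, temperature, age, time and speed).
#'
#' @param base One-row data frame with the seven factor columns.
#' @param factor Name of the factor to sweep (see [culture_factors()]).
#' @param values Numeric values the factor takes.
#' @return Data frame with `length(values)` rows, differing from `base` only
#'   in the swept factor.
#' @examples
#' base <- culture_condition(0.05, 6, 100, 28, 8, 8, 140)
#' one_factor_sweep(base, "ph", 1:14)
#' @export
one_factor_sweep <- function(base, factor, values) {
  factor <- match.arg(factor, culture_factors())
  out <- base[rep(1L, length(values)), , drop = FALSE]
  out[[factor]] <- values
  rownames(out) <- NULL
  out
}
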