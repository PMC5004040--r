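# Shared test helpers: independent oracles and small generated fixtures.

# Normal-equations least squares, independent of the package's QR path.
ne_solve <- function(M, y) unname(drop(solve(crossprod(M), crossprod(M, y))))

# Random records inside the corrected factor box, with an arbitrary smooth
# response unless `yield_fun` is given.
toy_records <- function(n, seed = 1, yield_fun = NULL) {
  set.seed(seed)
  b <- factor_bounds()
  m <- sapply(seq_len(nrow(b)), function(k) runif(n, b$lo[k], b$hi[k]))
  recs <- as.data.frame(matrix(m, nrow = n))
  names(recs) <- b$factor
  recs$yield <- if (is.null(yield_fun)) runif(n, 100, 2000)
                else yield_fun(recs)
  recs
}

# The published equation written out long-hand, term by term, as an
# arithmetic cross-check on the packaged model object.
handsum_yield <- function(x1, x2, x3, x4, x5, x6, x7) {
  3662.278 * x1 - 4263.361 * x1^2 +
    11737.986 * x2 - 999.556 * x2^2 -
    0.238 * x3^2 +
    3353.461 * x4 - 59.662 * x4^2 -
    420.854 * x5 + 42.495 * x5^2 +
    966.796 * x6 - 53.489 * x6^2 +
    27.213 * x7 - 0.234 * x7^2 +
    0.434 * x3 * x7 -
    86781.046
}
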