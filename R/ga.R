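# Gene-set genetic algorithm: a binary chromosome partitioned into one
# contiguous segment ("gene-set") per culture factor. Selection is
# roulette-wheel on shifted fitness, crossover is classical one-point at the
# bit level, and mutation replaces whole segments with fresh random segments
# rather than flipping single bits.

#' Binary encoding of the factor box
#'
#' Each factor gets a contiguous run of `bits` bits; a segment's unsigned
#' integer value `v` maps linearly onto its interval as
#' `lo + v * (hi - lo) / (2^bits - 1)`, so the all-zero segment decodes to
#' `lo` and the all-one segment to `hi`. Ten bits per factor quantize each
#' range into 1023 steps (at most 0.002 pH units), well below the precision
#' at which optima are reported.
#'
#' @param bounds A [factor_bounds()] box.
#' @param bits Bits per factor, scalar or per-factor vector, each >= 2.
#' @return Object of class `ga_encoding`.
#' @export
ga_encoding <- function(bounds = factor_bounds(), bits = 10) {
  stopifnot(inherits(bounds, "factor_bounds"))
  p <- nrow(bounds)
  bits <- rep_len(as.integer(bits), p)
  if (any(bits < 2)) stop("need at least 2 bits per factor", call. = FALSE)
  ends <- cumsum(bits)
  enc <- list(
    factors = bounds$factor, lo = bounds$lo, hi = bounds$hi, bits = bits,
    first = c(1L, utils::head(ends, -1) + 1L), last = ends,
    length = ends[p]
  )
  class(enc) <- "ga_encoding"
  enc
}

# L x p matrix turning a 0/1 chromosome matrix into decoded factor values by
# a single matrix product: column f holds 2^(b-1)..2^0 * step on f's segment
decode_weights <- function(enc) {
  W <- matrix(0, enc$length, length(enc$factors))
  for (f in seq_along(enc$factors)) {
    b <- enc$bits[f]
    W[enc$first[f]:enc$last[f], f] <-
      2^((b - 1):0) * (enc$hi[f] - enc$lo[f]) / (2^b - 1)
  }
  W
}

#' Encode a culture condition as a chromosome
#'
#' @param condition One-row data frame with the seven factor columns; must
#'   lie inside the encoding's bounds. Encoding rounds to the nearest
#'   quantization step, so `decode(encode(x))` differs from `x` by at most
#'   half a step per factor.
#' @param enc A [ga_encoding()].
#' @return Integer 0/1 vector of length `enc$length`.
#' @export
ga_encode <- function(condition, enc) {
  x <- as.numeric(condition[1, enc$factors])
  if (any(x < enc$lo - 1e-12) || any(x > enc$hi + 1e-12))
    stop("condition outside encoding bounds", call. = FALSE)
  bits <- integer(enc$length)
  for (f in seq_along(x)) {
    b <- enc$bits[f]
    v <- round((x[f] - enc$lo[f]) / (enc$hi[f] - enc$lo[f]) * (2^b - 1))
    bits[enc$first[f]:enc$last[f]] <- (v %/% 2^((b - 1):0)) %% 2
  }
  bits
}

#' Decode a chromosome to a culture condition
#'
#' @param bits Integer 0/1 vector (or matrix, one chromosome per row) of the
#'   encoding's length.
#' @param enc A [ga_encoding()].
#' @return Data frame of decoded conditions, one row per chromosome.
#' @export
ga_decode <- function(bits, enc) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
  if (ncol(bits) != enc$length)
    stop("chromosome length ", ncol(bits), " does not match encoding (",
         enc$length, ")", call. = FALSE)
  vals <- bits %*% decode_weights(enc)
  vals <- sweep(vals, 2, enc$lo, `+`)
  out <- as.data.frame(vals)
  names(out) <- enc$factors
  out
}

#' Roulette-wheel parent selection
#'
#' Draws parent indices with probability proportional to the shifted fitness
#' `f - min(f) + eps`, `eps = 1e-9 * (max(f) - min(f))`, which makes weights
#' non-negative for any (possibly negative) fitness; when all fitnesses are
#' equal the draw is uniform.
#'
#' @param fitness Numeric vector of cached population fitnesses.
#' @param n Number of draws.
#' @return Integer vector of `n` selected indices (with replacement).
#' @export
roulette_select <- function(fitness, n = 1) {
  if (!length(fitness)) stop("empty population", call. = FALSE)
  rng <- max(fitness) - min(fitness)
  if (rng <= 0) return(sample.int(length(fitness), n, replace = TRUE))
  w <- fitness - min(fitness) + 1e-9 * rng
  sample.int(length(fitness), n, replace = TRUE, prob = w)
}

#' One-point crossover
#'
#' With probability `rate`, swaps the tails of the two parent chromosomes at
#' a uniformly chosen internal bit position; otherwise returns the parents
#' unchanged. With `segment_boundaries = TRUE` the cut is restricted to
#' gene-set boundaries (requires `enc`).
#'
#' @param p1,p2 Parent 0/1 vectors of equal length.
#' @param rate Crossover probability in `[0, 1]`.
#' @param segment_boundaries Restrict cuts to segment boundaries.
#' @param enc Encoding, needed only when `segment_boundaries = TRUE`.
#' @return List of two child chromosomes.
#' @export
ga_crossover <- function(p1, p2, rate = 0.8, segment_boundaries = FALSE,
                         enc = NULL) {
  stopifnot(length(p1) == length(p2))
  if (stats::runif(1) >= rate) return(list(p1, p2))
  cuts <- if (segment_boundaries) {
    if (is.null(enc)) stop("enc required for segment-boundary crossover",
                           call. = FALSE)
    utils::head(enc$last, -1)
  } else seq_len(length(p1) - 1L)
  cut <- cuts[sample.int(length(cuts), 1)]
  i <- seq_len(cut)
  list(c(p1[i], p2[-i]), c(p2[i], p1[-i]))
}

#' Gene-set mutation
#'
#' Each of the per-factor segments is independently selected with
#' probability `rate`; a selected segment is replaced wholesale by a fresh
#' uniformly random bit segment of the same length. Bits outside selected
#' segments are untouched.
#'
#' @param bits Chromosome 0/1 vector.
#' @param rate Per-segment mutation probability in `[0, 1]`.
#' @param enc A [ga_encoding()].
#' @return Mutated chromosome.
#' @export
ga_mutate <- function(bits, rate, enc) {
  sel <- which(stats::runif(length(enc$factors)) < rate)
  for (f in sel) {
    idx <- enc$first[f]:enc$last[f]
    bits[idx] <- sample(c(0L, 1L), length(idx), replace = TRUE)
  }
  bits
}

#' Genetic-algorithm settings
#'
#' Defaults follow the published run: population 50, crossover rate 0.8,
#' per-segment mutation rate 0.01, roulette-wheel selection, at most 500
#' generations. One elite individual is copied unchanged into the next
#' generation (without elitism a roulette GA can lose its best solution;
#' disable with `elite_count = 0`).
#'
#' @param population_size Individuals per generation (>= 2).
#' @param crossover_rate Per-pair one-point crossover probability.
#' @param mutation_rate Per-segment, per-individual replacement probability.
#' @param elite_count Individuals copied unchanged each generation.
#' @param max_generations Generation cap.
#' @param fitness_limit Optional early-stop fitness threshold.
#' @param stall_generations Stop after this many generations without a
#'   best-fitness improvement greater than 1e-9.
#' @param segment_crossover Restrict crossover cuts to gene-set boundaries.
#' @param seed Optional RNG seed; identical seeds give bit-identical runs.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, crossover_rate = 0.8,
                      mutation_rate = 0.01, elite_count = 1,
                      max_generations = 500, fitness_limit = NULL,
                      stall_generations = 50, segment_crossover = FALSE,
                      seed = NULL) {
  stopifnot(population_size >= 2,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elite_count >= 0, elite_count < population_size,
            max_generations >= 1, stall_generations >= 1)
  structure(list(
    population_size = as.integer(population_size),
    crossover_rate = crossover_rate, mutation_rate = mutation_rate,
    elite_count = as.integer(elite_count),
    max_generations = as.integer(max_generations),
    fitness_limit = fitness_limit,
    stall_generations = as.integer(stall_generations),
    segment_crossover = isTRUE(segment_crossover), seed = seed
  ), class = "ga_config")
}

#' Maximize an objective with the gene-set genetic algorithm
#'
#' Runs the generational loop select -> crossover -> gene-set mutate, with
#' `elite_count` best individuals carried through unchanged, until the
#' generation cap, the fitness limit, or a stall (no best-fitness improvement
#' beyond 1e-9 for `stall_generations` generations).
#'
#' @param objective Either a fitted model (`rsm_fit` /
#'   [printed_yield_model()]), maximized via its [predict()] method, or a
#'   function mapping a data frame of conditions (one per row) to a numeric
#'   fitness vector.
#' @param bounds Feasible [factor_bounds()] box.
#' @param config A [ga_config()].
#' @param encoding A [ga_encoding()]; defaults to 10 bits per factor over
#'   `bounds`.
#' @return Object of class `ga_run`: `best_fitness`, `best_condition`
#'   (one-row data frame), `best_bits`, `trace` (data frame with columns
#'   `generation`, `best`, `mean`; `best` is the best fitness found so far,
#'   non-decreasing under elitism), `generations`, `stop_reason`.
#' @examples
#' run <- ga_optimize(printed_yield_model(),
#'                    config = ga_config(max_generations = 60, seed = 1))
#' run
#' @export
ga_optimize <- function(objective, bounds = factor_bounds(),
                        config = ga_config(),
                        encoding = ga_encoding(bounds)) {
  fitness_fun <- if (is.function(objective)) objective
                 else function(conds) predict(objective, conds)
  if (!is.null(config$seed)) set.seed(config$seed)
  np <- config$population_size
  L <- encoding$length
  W <- decode_weights(encoding)

  decode_pop <- function(pop) {
    vals <- sweep(pop %*% W, 2, encoding$lo, `+`)
    out <- as.data.frame(vals)
    names(out) <- encoding$factors
    out
  }
  eval_pop <- function(pop) {
    conds <- decode_pop(pop)
    f <- fitness_fun(conds)
    if (length(f) != nrow(pop) || !all(is.finite(f))) {
      bad <- if (length(f) == nrow(pop)) which(!is.finite(f))[1L] else 1L
      stop("objective returned a non-finite fitness at condition: ",
           paste(sprintf("%s=%g", names(conds), as.numeric(conds[bad, ])),
                 collapse = ", "), call. = FALSE)
    }
    f
  }

  pop <- matrix(sample(c(0L, 1L), np * L, replace = TRUE), nrow = np)
  fit <- eval_pop(pop)
  best_i <- which.max(fit)
  best_bits <- pop[best_i, ]; best_fit <- fit[best_i]
  trace_best <- numeric(config$max_generations)
  trace_mean <- numeric(config$max_generations)
  stall <- 0L
  stop_reason <- "max_generations"
  gen <- 0L

  for (gen in seq_len(config$max_generations)) {
    trace_best[gen] <- best_fit
    trace_mean[gen] <- mean(fit)
    if (!is.null(config$fitness_limit) && best_fit >= config$fitness_limit) {
      stop_reason <- "fitness_limit"; break
    }
    if (stall >= config$stall_generations) {
      stop_reason <- "stall"; break
    }
    if (gen == config$max_generations) break

    n_child <- np - config$elite_count
    parents <- roulette_select(fit, 2L * ceiling(n_child / 2))
    children <- matrix(0L, length(parents), L)
    for (k in seq_len(length(parents) / 2)) {
      pair <- ga_crossover(pop[parents[2 * k - 1], ], pop[parents[2 * k], ],
                           rate = config$crossover_rate,
                           segment_boundaries = config$segment_crossover,
                           enc = encoding)
      children[2 * k - 1, ] <- pair[[1]]
      children[2 * k, ] <- pair[[2]]
    }
    children <- children[seq_len(n_child), , drop = FALSE]
    for (k in seq_len(n_child))
      children[k, ] <- ga_mutate(children[k, ], config$mutation_rate,
                                 encoding)
    elite <- if (config$elite_count > 0)
      pop[order(fit, decreasing = TRUE)[seq_len(config$elite_count)], ,
          drop = FALSE]
    pop <- rbind(elite, children)
    fit <- eval_pop(pop)

    gi <- which.max(fit)
    if (fit[gi] > best_fit + 1e-9) {
      best_fit <- fit[gi]; best_bits <- pop[gi, ]; stall <- 0L
    } else stall <- stall + 1L
  }

  out <- list(
    best_fitness = best_fit,
    best_condition = ga_decode(best_bits, encoding),
    best_bits = best_bits,
    trace = data.frame(generation = seq_len(gen),
                       best = trace_best[seq_len(gen)],
                       mean = trace_mean[seq_len(gen)]),
    generations = gen,
    stop_reason = stop_reason,
    config = config,
    encoding = encoding
  )
  class(out) <- "ga_run"
  out
}

#' @export
print.ga_run <- function(x, ...) {
  cat("Gene-set GA run: ", x$generations, " generation(s), stopped on ",
      x$stop_reason, "\n", sep = "")
  cat("Best fitness: ", format(x$best_fitness, digits = 8), "\n", sep = "")
  cond <- x$best_condition
  cat(sprintf("  inoculum %.2f%%, pH %.2f, volume %.1f mL, %.2f degC,\n",
              cond$inoculum * 100, cond$ph, cond$volume, cond$temperature))
  cat(sprintf("  seed age %.2f d, fermentation %.2f d, %.1f r/min\n",
              cond$seed_age, cond$ferm_time, cond$rotation))
  invisible(x)
}

#' Plot the best-fitness trace of a GA run
#'
#' @param x A `ga_run`.
#' @param ... Passed to [plot()].
#' @export
plot.ga_run <- function(x, ...) {
  graphics::plot(x$trace$generation, x$trace$best, type = "l",
       xlab = "generation", ylab = "best fitness", ...)
  graphics::lines(x$trace$generation, x$trace$mean, lty = 2)
  graphics::legend("bottomright", c("best", "mean"), lty = 1:2, bty = "n")
  invisible(x)
}
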