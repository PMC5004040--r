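# The published 14-term flavonoid-yield equation, frozen verbatim as the
# canonical optimization objective, plus an exact box-constrained maximizer
# used as the genetic algorithm's oracle.

#' The published flavonoid-yield response surface
#'
#' The final stepwise-selected quadratic model of flavonoid yield in the
#' seven culture factors, with every coefficient frozen exactly as published
#' (three decimals; never refit). Factor order follows [culture_factors()]
#' with inoculum as a fraction. Because the stored coefficients are rounded,
#' predictions carry an irreducible relative error of a few tenths of a
#' percent.
#'
#' @return Object of class `c("yield_model", "rsm_fit")`; usable with
#'   [predict()], [ga_optimize()] and [analytic_box_maximum()].
#' @examples
#' m <- printed_yield_model()
#' predict(m, culture_condition(0.12, 5.8, 100, 28, 9, 9, 150))
#' @export
printed_yield_model <- function() {
  coefs <- c(
    "(Intercept)" = -86781.046,
    "x1" = 3662.278,  "x1^2" = -4263.361,
    "x2" = 11737.986, "x2^2" = -999.556,
    "x3^2" = -0.238,
    "x4" = 3353.461,  "x4^2" = -59.662,
    "x5" = -420.854,  "x5^2" = 42.495,
    "x6" = 966.796,   "x6^2" = -53.489,
    "x7" = 27.213,    "x7^2" = -0.234,
    "x3*x7" = 0.434
  )
  m <- list(
    terms = terms_by_label(setdiff(names(coefs), "(Intercept)")),
    coefficients = coefs,
    intercept = unname(coefs[["(Intercept)"]])
  )
  class(m) <- c("yield_model", "rsm_fit")
  m
}

#' @export
predict.yield_model <- function(object, newdata, ...) {
  validate_conditions(newdata)
  M <- build_design_matrix(newdata, object$terms)
  as.vector(M %*% object$coefficients)
}

#' @export
print.yield_model <- function(x, ...) {
  cat("Published flavonoid-yield equation (frozen coefficients):\n")
  print(x$coefficients)
  invisible(x)
}

# Pull the quadratic structure out of a coefficient vector keyed by x-index
# labels: linear part b, pure-quadratic diagonal a, interaction matrix q.
quadratic_structure <- function(fit) {
  p <- length(culture_factors())
  b <- numeric(p); a <- numeric(p); q <- matrix(0, p, p)
  cf <- fit$coefficients
  tt <- fit$terms
  for (k in seq_len(nrow(tt))) {
    val <- unname(cf[tt$label[k]])
    switch(tt$kind[k],
      linear      = b[tt$i[k]] <- val,
      square      = a[tt$i[k]] <- val,
      interaction = { q[tt$i[k], tt$j[k]] <- val
                      q[tt$j[k], tt$i[k]] <- val }
    )
  }
  list(b = b, a = a, q = q,
       c0 = unname(cf[["(Intercept)"]]))
}

# max of a*x^2 + b*x over [lo, hi]: endpoints plus interior vertex
max_quad_1d <- function(a, b, lo, hi) {
  xs <- c(lo, hi)
  if (a != 0) {
    v <- -b / (2 * a)
    if (v > lo && v < hi) xs <- c(xs, v)
  }
  vals <- a * xs^2 + b * xs
  k <- which.max(vals)
  c(x = xs[k], value = vals[k])
}

# max of ai*x^2 + bi*x + aj*y^2 + bj*y + q*x*y over [loi,hii] x [loj,hij]:
# interior stationary point, the four edges (1-D quadratics), the corners
max_quad_2d <- function(ai, bi, aj, bj, q, loi, hii, loj, hij) {
  cand <- rbind(expand.grid(x = c(loi, hii), y = c(loj, hij)))
  H <- matrix(c(2 * ai, q, q, 2 * aj), 2, 2)
  if (abs(det(H)) > 1e-12) {
    s <- solve(H, c(-bi, -bj))
    if (s[1] > loi && s[1] < hii && s[2] > loj && s[2] < hij)
      cand <- rbind(cand, data.frame(x = s[1], y = s[2]))
  }
  for (x0 in c(loi, hii)) {             # edges x = const: quadratic in y
    e <- max_quad_1d(aj, bj + q * x0, loj, hij)
    cand <- rbind(cand, data.frame(x = x0, y = e[["x"]]))
  }
  for (y0 in c(loj, hij)) {             # edges y = const: quadratic in x
    e <- max_quad_1d(ai, bi + q * y0, loi, hii)
    cand <- rbind(cand, data.frame(x = e[["x"]], y = y0))
  }
  vals <- ai * cand$x^2 + bi * cand$x + aj * cand$y^2 + bj * cand$y +
    q * cand$x * cand$y
  k <- which.max(vals)
  list(x = cand$x[k], y = cand$y[k], value = vals[k])
}

#' Exact maximum of a quadratic surface over a factor box
#'
#' Closed-form maximization of a fitted second-order surface over the
#' feasible box, used as the independent oracle against which the genetic
#' algorithm is validated. Factors not coupled by interaction terms are
#' maximized as one-dimensional quadratics (interior vertex or boundary);
#' factors coupled pairwise are maximized exactly over their rectangle
#' (interior stationary point, four edges, corners). Surfaces whose
#' interaction graph couples three or more factors in one block are not
#' supported.
#'
#' @param model An `rsm_fit` or [printed_yield_model()].
#' @param bounds A [factor_bounds()] box.
#' @return List with `condition` (one-row data frame at the arg-max) and
#'   `value` (the maximum predicted yield).
#' @examples
#' analytic_box_maximum(printed_yield_model(), factor_bounds())
#' @export
analytic_box_maximum <- function(model, bounds = factor_bounds()) {
  stopifnot(inherits(bounds, "factor_bounds"))
  if (any(bounds$hi - bounds$lo <= 0))
    stop("degenerate bounds", call. = FALSE)
  qs <- quadratic_structure(model)
  p <- length(qs$b)
  # connected components of the interaction graph
  comp <- seq_len(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) if (qs$q[i, j] != 0)
    comp[comp == comp[j]] <- comp[i]
  xopt <- numeric(p)
  total <- qs$c0
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) == 1L) {
      i <- members
      m <- max_quad_1d(qs$a[i], qs$b[i], bounds$lo[i], bounds$hi[i])
      xopt[i] <- m[["x"]]; total <- total + m[["value"]]
    } else if (length(members) == 2L) {
      i <- members[1]; j <- members[2]
      m <- max_quad_2d(qs$a[i], qs$b[i], qs$a[j], qs$b[j], qs$q[i, j],
                       bounds$lo[i], bounds$hi[i], bounds$lo[j], bounds$hi[j])
      xopt[i] <- m$x; xopt[j] <- m$y; total <- total + m$value
    } else {
      stop("interaction block with ", length(members),
           " coupled factors; closed-form maximizer supports blocks of ",
           "at most two", call. = FALSE)
    }
  }
  cond <- as.data.frame(as.list(stats::setNames(xopt, culture_factors())))
  list(condition = cond, value = total)
}
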