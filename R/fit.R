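# Ordinary least squares for response-surface term sets, with the ANOVA
# decomposition reported for such fits (regression/residual sums of squares,
# F, R, R-squared, residual standard error).

#' Fit a response surface by ordinary least squares
#'
#' Solves the least-squares problem for the given term set (plus intercept)
#' via QR decomposition. The design must have full column rank and at least
#' as many records as columns; rank-deficient designs are rejected with the
#' offending columns named rather than silently aliased.
#'
#' @param records Data frame with the seven factor columns and a `yield`
#'   column (e.g. from [filter_records()] or [simulate_surface()]).
#' @param terms An `rsm_terms` term set ([candidate_terms()],
#'   [terms_by_label()]); may have zero rows for an intercept-only fit.
#' @return Object of class `rsm_fit` with components `terms`,
#'   `coefficients` (named, intercept first), `intercept`, `residuals`,
#'   `fitted.values`, `sigma`, `se`, `vcov`, `df.residual`, `n_obs`.
#' @seealso [rsm_stepwise()], [rsm_anova()]
#' @examples
#' recs <- filter_records(phellinus45())
#' fit <- rsm_fit(recs, terms_by_label(c("x2", "x2^2", "x1", "x1^2")))
#' coef(fit)
#' @export
rsm_fit <- function(records, terms) {
  y <- records$yield
  if (is.null(y)) stop("records must contain a 'yield' column", call. = FALSE)
  M <- build_design_matrix(records, terms)
  n <- nrow(M); p <- ncol(M)
  if (n < p)
    stop("cannot fit ", p, " coefficients to ", n,
         " records; reduce the term set", call. = FALSE)
  qx <- qr(M)
  if (qx$rank < p) {
    dropped <- colnames(M)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(M %*% beta)
  res <- y - fitted
  df_res <- n - p
  rss <- sum(res^2)
  sigma2 <- if (df_res > 0) rss / df_res else NA_real_
  Rinv <- backsolve(qr.R(qx), diag(p))
  XtXinv <- tcrossprod(Rinv)
  ord <- order(qx$pivot)
  XtXinv <- XtXinv[ord, ord, drop = FALSE]
  dimnames(XtXinv) <- list(colnames(M), colnames(M))
  fit <- list(
    terms = terms,
    coefficients = beta,
    intercept = unname(beta["(Intercept)"]),
    residuals = res,
    fitted.values = fitted,
    sigma = sqrt(sigma2),
    se = sqrt(diag(XtXinv) * sigma2),
    vcov = XtXinv * sigma2,
    df.residual = df_res,
    n_obs = n,
    y = y
  )
  class(fit) <- "rsm_fit"
  fit
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
residuals.rsm_fit <- function(object, ...) object$residuals

#' @export
fitted.rsm_fit <- function(object, ...) object$fitted.values

#' Predict flavonoid yield at new culture conditions
#'
#' @param object An `rsm_fit`.
#' @param newdata Data frame with the seven factor columns (inoculum as a
#'   fraction).
#' @param ... Unused.
#' @return Numeric vector of predicted yields (no clamping).
#' @export
predict.rsm_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  M <- build_design_matrix(newdata, object$terms)
  as.vector(M %*% object$coefficients)
}

#' Simulate responses from a fitted surface
#'
#' Draws Gaussian responses around the fitted surface with the residual
#' standard error (or a supplied `sd`), the parametric-bootstrap companion to
#' [simulate_surface()].
#'
#' @param object An `rsm_fit`.
#' @param nsim Number of response vectors.
#' @param seed Optional RNG seed.
#' @param newdata Conditions to simulate at (default: the fitted records).
#' @param sd Noise standard deviation (default: `object$sigma`).
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated yields.
#' @export
simulate.rsm_fit <- function(object, nsim = 1, seed = NULL, newdata,
                             sd = object$sigma, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- if (missing(newdata)) object$fitted.values
        else predict(object, newdata)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.rsm_fit <- function(x, digits = 4, ...) {
  cat("Response-surface fit: ", nrow(x$terms), " term(s) + intercept, n = ",
      x$n_obs, "\n", sep = "")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.rsm_fit <- function(object, ...) {
  tval <- object$coefficients / object$se
  ctab <- cbind(
    Estimate = object$coefficients,
    `Std. Error` = object$se,
    `t value` = tval,
    `Pr(>|t|)` = 2 * stats::pt(abs(tval), object$df.residual,
                               lower.tail = FALSE)
  )
  out <- list(coefficients = ctab, anova = rsm_anova(object),
              steps = object$steps)
  class(out) <- "summary.rsm_fit"
  out
}

#' @export
print.summary.rsm_fit <- function(x, ...) {
  stats::printCoefmat(x$coefficients)
  cat("\n")
  print(x$anova)
  if (!is.null(x$steps))
    cat("\nStepwise path:", paste(x$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' ANOVA decomposition of a response-surface fit
#'
#' Splits the total sum of squares (about the mean) into regression and
#' residual components and reports the overall F statistic, multiple
#' correlation R, R-squared and residual standard error, with degrees of
#' freedom `df_regression = #(non-intercept terms)`,
#' `df_residual = n - df_regression - 1`.
#'
#' @param fit An `rsm_fit`.
#' @return Object of class `rsm_anova`: list with `ss_regression`,
#'   `ss_residual`, `ss_total`, `df_regression`, `df_residual`, `df_total`,
#'   `f_stat`, `p_value`, `r`, `r_squared`, `std_error`.
#' @export
rsm_anova <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  n <- fit$n_obs
  df_reg <- nrow(fit$terms)
  df_res <- n - df_reg - 1L
  if (df_res <= 0L)
    stop("no residual degrees of freedom (n = ", n, ", terms = ", df_reg,
         ")", call. = FALSE)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((fit$y - mean(fit$y))^2)
  ss_reg <- ss_tot - ss_res
  f <- if (df_reg > 0) (ss_reg / df_reg) / (ss_res / df_res) else NA_real_
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  out <- list(
    ss_regression = ss_reg, ss_residual = ss_res, ss_total = ss_tot,
    df_regression = df_reg, df_residual = df_res, df_total = n - 1L,
    f_stat = f,
    p_value = if (is.na(f)) NA_real_ else
      stats::pf(f, df_reg, df_res, lower.tail = FALSE),
    r = if (is.na(r2)) NA_real_ else sqrt(max(r2, 0)),
    r_squared = r2,
    std_error = sqrt(ss_res / df_res)
  )
  class(out) <- "rsm_anova"
  out
}

#' @export
print.rsm_anova <- function(x, ...) {
  tab <- data.frame(
    `Sum of squares` = c(x$ss_regression, x$ss_residual, x$ss_total),
    df = c(x$df_regression, x$df_residual, x$df_total),
    `Mean square` = c(x$ss_regression / max(x$df_regression, 1),
                      x$ss_residual / x$df_residual, NA),
    F = c(x$f_stat, NA, NA),
    R = c(x$r, NA, NA),
    `R squared` = c(x$r_squared, NA, NA),
    `Std. error` = c(x$std_error, NA, NA),
    check.names = FALSE,
    row.names = c("Regression", "Residual", "Total")
  )
  print(format(tab, digits = 6, nsmall = 2))
  invisible(x)
}
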