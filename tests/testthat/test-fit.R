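test_that("intercept-only fit returns the response mean", {
  recs <- toy_records(12, seed = 3)
  fit <- rsm_fit(recs, candidate_terms()[0, ])
  expect_equal(unname(coef(fit)), mean(recs$yield))
})

test_that("OLS matches the normal-equations oracle and recovers exactly", {
  # five-record toy against an independent normal-equations solve
  recs <- toy_records(5, seed = 7)
  tt <- terms_by_label(c("x1", "x2", "x2^2"))
  fit <- rsm_fit(recs, tt)
  M <- build_design_matrix(recs, tt)
  expect_equal(unname(coef(fit)), ne_solve(M, recs$yield),
               tolerance = 1e-8)
  # residuals orthogonal to every design column
  expect_lt(max(abs(crossprod(M, residuals(fit)))) /
              max(abs(crossprod(M, recs$yield))), 1e-6)

  # noise-free responses from known coefficients are recovered
  truth <- c(5, -2, 40, -3.5)  # intercept, x1, x2, x2^2
  recs2 <- toy_records(30, seed = 11)
  recs2$yield <- drop(build_design_matrix(recs2, tt) %*% truth)
  fit2 <- rsm_fit(recs2, tt)
  expect_equal(unname(coef(fit2)), truth, tolerance = 1e-8)
  expect_equal(unname(predict(fit2, recs2)), recs2$yield, tolerance = 1e-8)
})

test_that("degenerate designs are rejected with named columns", {
  recs <- toy_records(10, seed = 5)
  recs$volume <- 80  # constant factor: x3 collinear with the intercept
  expect_error(rsm_fit(recs, terms_by_label(c("x3", "x4"))),
               "rank deficient; collinear column")
  expect_error(rsm_fit(toy_records(3), terms_by_label(c("x1", "x2", "x4"))),
               "reduce the term set")
})

test_that("the ANOVA block decomposes the total sum of squares", {
  recs <- toy_records(25, seed = 9)
  tt <- candidate_terms()[1:14, ]
  fit <- rsm_fit(recs, tt)
  a <- rsm_anova(fit)
  # df bookkeeping: 14 regression + 10 residual = 24 total at n = 25
  expect_equal(a$df_regression, 14)
  expect_equal(a$df_residual, 10)
  expect_equal(a$df_total, 24)
  expect_equal(a$df_regression + a$df_residual, a$df_total)
  expect_equal(a$ss_regression + a$ss_residual, a$ss_total,
               tolerance = 1e-9)
  expect_true(a$r_squared >= 0 && a$r_squared <= 1)
  expect_equal(a$r, sqrt(a$r_squared))

  # F on a six-point toy equals the textbook formula computed directly
  recs6 <- toy_records(6, seed = 13)
  tt6 <- terms_by_label(c("x2", "x5"))
  fit6 <- rsm_fit(recs6, tt6)
  a6 <- rsm_anova(fit6)
  beta <- ne_solve(build_design_matrix(recs6, tt6), recs6$yield)
  res <- recs6$yield - drop(build_design_matrix(recs6, tt6) %*% beta)
  ss_res <- sum(res^2)
  ss_tot <- sum((recs6$yield - mean(recs6$yield))^2)
  expect_equal(a6$f_stat, ((ss_tot - ss_res) / 2) / (ss_res / 3),
               tolerance = 1e-10)
  expect_equal(a6$std_error, sqrt(ss_res / 3), tolerance = 1e-10)

  # perfect fit: R^2 = 1, zero residual SS
  recs6$yield <- drop(build_design_matrix(recs6, tt6) %*% c(1, 2, 3))
  ap <- rsm_anova(rsm_fit(recs6, tt6))
  expect_equal(ap$r_squared, 1, tolerance = 1e-12)
  expect_equal(ap$ss_residual, 0, tolerance = 1e-6)
  expect_error(rsm_anova(rsm_fit(toy_records(2, 2), terms_by_label("x1"))),
               "degrees of freedom")
})

test_that("adding a column never increases the residual sum of squares", {
  recs <- toy_records(40, seed = 17)
  labels <- c("x1", "x2", "x2^2", "x3*x7", "x5", "x6^2")
  rss <- sapply(seq_along(labels), function(k)
    sum(residuals(rsm_fit(recs, terms_by_label(labels[1:k])))^2))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("R^2 is invariant under affine factor rescaling", {
  recs <- toy_records(30, seed = 19)
  tt <- terms_by_label(c("x4", "x4^2"))
  r2 <- rsm_anova(rsm_fit(recs, tt))$r_squared
  scaled <- recs
  scaled$temperature <- recs$temperature * 1.8 + 32  # Celsius -> Fahrenheit
  r2s <- rsm_anova(rsm_fit(scaled, tt))$r_squared
  expect_equal(r2, r2s, tolerance = 1e-9)
})

test_that("summary and simulate methods work on a fit", {
  recs <- toy_records(30, seed = 23)
  fit <- rsm_fit(recs, terms_by_label(c("x2", "x2^2")))
  s <- summary(fit)
  expect_equal(dim(s$coefficients), c(3L, 4L))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(30L, 3L))
  sim0 <- simulate(fit, nsim = 2, seed = 2, sd = 0)
  expect_equal(sim0$sim_1, fitted(fit))
})
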