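test_that("noise-free quadratic responses are recovered exactly", {
  f <- three_factors()
  truth <- true_coded_model(f)
  d <- simulate_response(generate_bbd(f, n_center = 3),
                         surface_spec(truth, noise_sd = 0), seed = 1)
  fit_c <- fit_quadratic(d, "coded")
  expect_equal(fit_c$coef, truth$coef, tolerance = 1e-8)
  # same model through the actual-unit route
  fit_a <- fit_quadratic(d, "actual")
  expect_equal(convert_units(fit_a, "coded")$coef, truth$coef,
               tolerance = 1e-8)
  # and a perfect fit
  an <- quad_anova(fit_c, d)
  expect_lt(an$table$ss[an$table$source == "Residual"], 1e-16)
  expect_equal(an$r2, 1, tolerance = 1e-10)
})

test_that("unit conversion is an exact involution", {
  m <- fit_quadratic(prac_design(), "actual")
  mc <- convert_units(m, "coded")
  expect_equal(convert_units(mc, "actual")$coef, m$coef, tolerance = 1e-12)
  # both parameterizations predict identically
  s <- design_settings(prac_design())
  expect_equal(predict(mc, code_settings(s, m$factors)), predict(m, s),
               tolerance = 1e-10)
})

test_that("prediction agrees with term-by-term summation", {
  m <- fit_quadratic(prac_design(), "actual")
  withr::with_seed(42, {
    for (i in 1:100) {
      x <- stats::runif(4, m$factors$low, m$factors$high)
      expect_equal(predict(m, x), brute_force_predict(m, x),
                   tolerance = 1e-12)
    }
  })
  zero <- quadratic_model(0, rep(0, 4), rep(0, 6), rep(0, 4),
                          units = "actual", factors = prac_factors())
  expect_equal(predict(zero, c(18, 80, 90, 400)), 0)
})

test_that("ANOVA bookkeeping is self-consistent on the fixture", {
  d <- prac_design()
  m <- fit_quadratic(d)
  an <- quad_anova(m, d)
  tab <- an$table
  g <- function(src, col) tab[[col]][tab$source == src]
  # SS additivity and degrees of freedom
  expect_equal(g("Model", "ss") + g("Residual", "ss"), g("Cor Total", "ss"),
               tolerance = 1e-8)
  expect_equal(g("Lack of Fit", "ss") + g("Pure Error", "ss"),
               g("Residual", "ss"), tolerance = 1e-10)
  expect_equal(g("Cor Total", "df"), 28L)
  expect_equal(g("Model", "df") + g("Residual", "df"), 28L)
  # every partial SS is positive and bounded by the model SS (exact
  # additivity does not hold: the pure-quadratic columns of a BBD are not
  # mutually orthogonal)
  terms <- setdiff(tab$source, c("Model", "Residual", "Lack of Fit",
                                 "Pure Error", "Cor Total"))
  term_ss <- vapply(terms, g, numeric(1), col = "ss")
  expect_true(all(term_ss > 0 & term_ss < g("Model", "ss")))
  # ANOVA R2 equals the generic metric on actual vs fitted
  fitted <- predict(m, design_settings(d))
  expect_equal(an$r2, r_squared(d$runs$response, fitted), tolerance = 1e-10)
})

test_that("ANOVA warns when no replicate runs exist", {
  f <- three_factors()
  d <- simulate_response(generate_bbd(f, n_center = 1),
                         surface_spec(true_coded_model(f), 0.1), seed = 2)
  m <- fit_quadratic(d)
  expect_warning(an <- quad_anova(m, d), "pure error undefined")
  expect_false(an$pure_error_available)
  expect_false("Lack of Fit" %in% an$table$source)
  # the lone center point is fitted exactly (leverage 1), so the
  # leave-one-out statistics are undefined rather than silently wrong
  expect_error(press_stats(d), "leverage of 1.*PRESS undefined")
  expect_true(is.na(an$pred_r2))
})

test_that("rank-deficient designs raise a singularity error naming terms", {
  f <- rbind(factor_spec("a", "", 0, 2), factor_spec("b", "", 0, 2),
             factor_spec("c", "", 0, 2))
  # factor c duplicates factor b run-for-run -> collinear columns
  s2 <- as.matrix(expand.grid(a = c(0, 1, 2), b = c(0, 1, 2)))
  s2 <- rbind(s2, s2)  # enough runs for the 10-term basis, still collinear
  d <- design_table(f, cbind(s2, c = s2[, "b"]),
                    response = seq_len(nrow(s2)))
  expect_error(fit_quadratic(d), "singular design: collinear")
})

test_that("PRESS matches explicit leave-one-out refits", {
  f <- three_factors()
  d <- simulate_response(generate_bbd(f, n_center = 3),
                         surface_spec(true_coded_model(f), 0.3), seed = 7)
  ps <- press_stats(d)
  # brute-force oracle: refit without row i, predict row i
  y <- d$runs$response
  coded <- code_settings(design_settings(d), d$factors)
  mm <- quad_model_matrix(coded, d$factors$name)
  loo <- vapply(seq_along(y), function(i) {
    fit <- stats::lm.fit(mm[-i, , drop = FALSE], y[-i])
    y[i] - sum(mm[i, ] * fit$coefficients)
  }, numeric(1))
  expect_equal(ps$press, sum(loo^2), tolerance = 1e-8)

  # duplicated noise-free data: every held-out point is still interpolated
  d0 <- simulate_response(generate_bbd(f, n_center = 3),
                          surface_spec(true_coded_model(f), 0), seed = 1)
  s0 <- design_settings(d0)
  dd <- design_table(f, rbind(s0, s0),
                     response = rep(d0$runs$response, 2))
  ps0 <- press_stats(dd)
  expect_lt(ps0$press, 1e-16)
  expect_equal(ps0$pred_r2, 1, tolerance = 1e-10)
})

test_that("surface maximization handles interior and corner optima", {
  f2 <- rbind(factor_spec("u", "", 0, 5), factor_spec("v", "", 0, 5))
  # concave bowl centred at (2, 2): maximum 0 in the interior
  bowl <- quadratic_model(-8, c(4, 4), 0, c(-1, -1), units = "actual",
                          factors = f2)
  opt <- optimize_surface(bowl, cbind(c(0, 0), c(5, 5)))
  expect_equal(unname(opt$settings), c(2, 2), tolerance = 1e-6)
  expect_equal(opt$value, 0, tolerance = 1e-10)
  # pure linear surface: maximizer at the corner given by coefficient signs
  lin <- quadratic_model(0, c(3, -2), 0, c(0, 0), units = "actual",
                         factors = f2)
  opt2 <- optimize_surface(lin, cbind(c(0, 0), c(5, 5)))
  expect_equal(unname(opt2$settings), c(5, 0), tolerance = 1e-8)
})

test_that("fixture-surface maximum agrees with a dense grid oracle", {
  m <- fit_quadratic(prac_design(), "actual")
  opt <- optimize_surface(m)
  grids <- lapply(seq_len(4), function(j) {
    seq(m$factors$low[j], m$factors$high[j], length.out = 41)
  })
  pts <- as.matrix(expand.grid(grids))
  vals <- predict(m, pts)
  expect_gte(opt$value, max(vals) - 1e-3)
  # the optimizer can only do better than the grid (same box)
  expect_lte(max(vals), opt$value + 1e-10)
})

test_that("parameter recovery error shrinks to zero with the noise", {
  f <- prac_factors()
  truth <- convert_units(prac_printed_model(), "coded")
  bbd <- generate_bbd(f, n_center = 5)
  err <- vapply(c(0.3, 0.1, 0.03, 0), function(s) {
    e <- vapply(1:20, function(r) {
      d <- simulate_response(bbd, surface_spec(truth, s), seed = 1000 + r)
      sqrt(mean((fit_quadratic(d, "coded")$coef - truth$coef)^2))
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(all(diff(err) < 0))   # monotone in shrinking noise
  expect_lt(err[4], 1e-10)          # exact at zero noise
})
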