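test_that("the Box-Behnken construction has the right run structure", {
  d4 <- generate_bbd(prac_factors(), n_center = 5)
  expect_equal(nrow(d4$runs), 29L)               # 4*C(4,2) + 5
  expect_equal(sum(is_center_run(d4)), 5L)
  d3 <- generate_bbd(three_factors(), n_center = 3)
  expect_equal(nrow(d3$runs), 15L)               # 4*C(3,2) + 3
  # every non-center run has exactly two factors off center
  coded <- to_coded(d4)
  off <- rowSums(coded != 0)
  expect_true(all(off[!is_center_run(d4)] == 2))
  expect_error(generate_bbd(prac_factors()[1:2, ]), "3-7 factors")
  # deterministic construction: same call, same table
  expect_identical(generate_bbd(prac_factors(), 5)$runs, d4$runs)
})

test_that("simulation is exact at zero noise and seeded otherwise", {
  f <- three_factors()
  truth <- true_coded_model(f)
  bbd <- generate_bbd(f, n_center = 3)
  d0 <- simulate_response(bbd, surface_spec(truth, 0), seed = 1)
  mu <- predict(convert_units(truth, "actual"), design_settings(bbd))
  expect_equal(d0$runs$response, mu, tolerance = 1e-12)
  d1 <- simulate_response(bbd, surface_spec(truth, 0.2), seed = 5)
  d2 <- simulate_response(bbd, surface_spec(truth, 0.2), seed = 5)
  expect_identical(d1$runs$response, d2$runs$response)
  expect_false(identical(d0$runs$response, d1$runs$response))
})

test_that("simulated noise has the requested scale", {
  f <- three_factors()
  centers <- design_table(f, matrix(rep(f$center, each = 1000), 1000, 3))
  d <- simulate_response(centers, surface_spec(true_coded_model(f), 0.1),
                         seed = 99)
  expect_gt(stats::sd(d$runs$response), 0.09)
  expect_lt(stats::sd(d$runs$response), 0.11)
})

test_that("a smooth non-quadratic perturbation shows up as lack of fit", {
  f <- prac_factors()
  truth <- convert_units(prac_printed_model(), "coded")
  bbd <- generate_bbd(f, n_center = 5)
  pert <- surface_spec(truth, 0.05,
                       perturbation = list(amplitude = 1, factors = c(2, 3)))
  d <- simulate_response(bbd, pert, seed = 3)
  m <- fit_quadratic(d)
  an <- quad_anova(m, d)
  lof_p <- an$table$p[an$table$source == "Lack of Fit"]
  expect_lt(lof_p, 0.01)
})

test_that("study-like simulations recover the generating surface", {
  spec <- paper_like_spec()
  expect_equal(spec$noise_sd, sqrt(0.058))
  f <- prac_factors()
  bbd <- generate_bbd(f, n_center = 5)
  # zero noise: perfect fit
  d0 <- simulate_response(bbd, surface_spec(spec$true_model, 0), seed = 1)
  expect_equal(quad_anova(fit_quadratic(d0), d0)$r2, 1, tolerance = 1e-10)
  # Monte-Carlo parameter recovery: each coefficient within 3 simulation
  # standard errors of its true value (coded units, 200 replicates)
  truth <- convert_units(spec$true_model, "coded")
  reps <- vapply(1:200, function(r) {
    d <- simulate_response(bbd, spec, seed = 20000 + r)
    fit_quadratic(d, "coded")$coef
  }, numeric(15))
  est_mean <- rowMeans(reps)
  est_se <- apply(reps, 1, stats::sd) / sqrt(ncol(reps))
  expect_true(all(abs(est_mean - truth$coef) < 3 * est_se))
  # and the fitted model is detectable: F beats the 5% critical value in
  # at least 80% of replicates
  fcrit <- stats::qf(0.95, 14, 14)
  fs <- vapply(1:200, function(r) {
    d <- simulate_response(bbd, spec, seed = 20000 + r)
    an <- quad_anova(fit_quadratic(d), d)
    an$table$f[an$table$source == "Model"]
  }, numeric(1))
  expect_gte(mean(fs > fcrit), 0.8)
})

test_that("coefficient error grows with the noise level", {
  f <- prac_factors()
  truth <- convert_units(prac_printed_model(), "coded")
  bbd <- generate_bbd(f, n_center = 5)
  err <- vapply(c(0.05, 0.1, 0.2), function(s) {
    mean(vapply(1:100, function(r) {
      d <- simulate_response(bbd, surface_spec(truth, s), seed = 500 + r)
      mean(abs(fit_quadratic(d, "coded")$coef - truth$coef))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) > 0))  # rank correlation 1 over the three levels
})
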