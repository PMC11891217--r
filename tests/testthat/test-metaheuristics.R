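test_that("the GA solves the 5-d sphere within the study's budget", {
  res <- ga_minimize(function(x) sum(x^2), dim = 5,
                     ga_config(bounds = c(-5, 5), seed = 1))
  expect_lt(res$value, 0.05)
  expect_equal(nrow(res$trace), 50L)
})

test_that("GA results are enumeration-consistent and seed-deterministic", {
  # log every evaluated point: the reported best must be the best evaluated
  evals <- new.env()
  evals$v <- numeric(0)
  obj <- function(x) {
    val <- sum((x - 1)^2)
    evals$v <- c(evals$v, val)
    val
  }
  res <- ga_minimize(obj, dim = 2,
                     ga_config(pop_size = 2, generations = 1,
                               bounds = c(-2, 2), seed = 9))
  expect_equal(res$value, min(evals$v))

  cfg <- ga_config(bounds = c(-3, 3), seed = 11)
  r1 <- ga_minimize(function(x) sum(abs(x)), 3, cfg)
  r2 <- ga_minimize(function(x) sum(abs(x)), 3, cfg)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trace, r2$trace)

  # constant objective: best value is that constant
  rc <- ga_minimize(function(x) 4.2, 3, ga_config(seed = 2))
  expect_equal(rc$value, 4.2)
})

test_that("non-finite objective values are penalized, not fatal", {
  spiky <- function(x) if (x[1] > 0) NaN else sum(x^2)
  res <- ga_minimize(spiky, 2, ga_config(seed = 3))
  expect_true(is.finite(res$value))
})

test_that("best-so-far traces are monotone for GA and ACO", {
  for (s in 1:3) {
    g <- ga_minimize(function(x) sum(sin(x) + x^2), 4,
                     ga_config(bounds = c(-4, 4), seed = s))
    expect_true(all(diff(g$trace$best) <= 0))
    a <- aco_minimize(function(x) sum(sin(x) + x^2), 4,
                      aco_config(seed = s))
    expect_true(all(diff(a$trace$best) <= 0))
    expect_lte(a$trace$best[nrow(a$trace)], a$trace$best[1])
  }
})

test_that("with no crossover or mutation, elitism keeps the population best", {
  evals <- new.env()
  evals$v <- numeric(0)
  obj <- function(x) {
    val <- sum(x^2)
    evals$v <- c(evals$v, val)
    val
  }
  np <- 6L
  ga_minimize(obj, 3, ga_config(pop_size = np, generations = 10,
                                p_crossover = 0, p_mutation = 0,
                                bounds = c(-2, 2), seed = 4))
  per_gen <- split(evals$v, ceiling(seq_along(evals$v) / np))
  gen_best <- vapply(per_gen, min, numeric(1))
  expect_true(all(diff(gen_best) <= 1e-12))
})

test_that("ACO finds an on-grid optimum exactly", {
  # grid over [-2, 2] with 41 candidates has spacing 0.1: 0.7 is on it
  res <- aco_minimize(function(x) abs(x[1] - 0.7), 1,
                      aco_config(bounds = c(-2, 2),
                                 n_candidates_per_dim = 41, seed = 1))
  expect_equal(res$value, 0)
  expect_equal(res$par, 0.7)
})

test_that("fully greedy ants all walk the same path", {
  res <- aco_minimize(function(x) sum(x^2), 3,
                      aco_config(q0 = 1, iterations = 10, seed = 2))
  # every ant in an iteration is identical, so the mean equals the best
  expect_equal(res$trace$mean, res$trace$best)
})

test_that("hybrid trainers honor their stage contracts", {
  dat <- fixture_training_data()
  gb <- train_ga_bp(dat, 4, ga_config(bounds = c(-1, 1), seed = 1),
                    train_config(seed = 1))
  expect_gte(gb$report$ga_value, gb$report$final_mse)
  gb2 <- train_ga_bp(dat, 4, ga_config(bounds = c(-1, 1), seed = 1),
                     train_config(seed = 1))
  expect_identical(flatten_params(gb$params), flatten_params(gb2$params))

  hy <- train_ga_aco_bp(dat, 4, aco = aco_config(bounds = c(-1, 1), seed = 1),
                        bp = train_config(seed = 1))
  expect_gte(hy$report$stage2_value, hy$report$final_mse)
  expect_true(hy$report$aco_last_improved >= 1)
  expect_true(all(diff(hy$report$aco_trace$best) <= 0))
})
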