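#' Genetic-algorithm configuration
#'
#' Defaults are the budget used in the extraction study: population 30, 50
#' generations, crossover probability 0.8, mutation probability 0.2. The
#' operators are a standard real-coded set: tournament selection (size 2),
#' arithmetic blend crossover, per-gene Gaussian mutation with standard
#' deviation 10% of the gene's bound width, and one-elite elitism (which
#' makes the best-so-far trace provably monotone).
#'
#' @param pop_size Population size (>= 2).
#' @param generations Number of generations.
#' @param p_crossover,p_mutation Crossover probability (per mating) and
#'   mutation probability (per gene), both in \[0, 1\].
#' @param bounds Two-column matrix (low, high) per gene, or a length-2
#'   vector recycled over genes.
#' @param seed Integer seed.
#' @return A list of class `"ga_config"`.
#' @export
ga_config <- function(pop_size = 30, generations = 50, p_crossover = 0.8,
                      p_mutation = 0.2, bounds = c(-3, 3), seed = 1) {
  stopifnot(pop_size >= 2, generations >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 bounds = bounds, seed = as.integer(seed)),
            class = "ga_config")
}

expand_bounds <- function(bounds, dim) {
  b <- if (is.null(dim(bounds))) {
    matrix(rep(bounds, each = dim), dim, 2)
  } else {
    as.matrix(bounds)
  }
  stopifnot(nrow(b) == dim, ncol(b) == 2, all(b[, 1] < b[, 2]))
  b
}

penalize <- function(v) ifelse(is.finite(v), v, 1e12)

#' Minimize a function with a real-coded genetic algorithm
#'
#' @param objective Function mapping a numeric vector of length `dim` to a
#'   scalar; non-finite values are penalized, not fatal.
#' @param dim Number of genes.
#' @param config A [ga_config()].
#' @return List with `par` (best vector found), `value`, and `trace`, a
#'   data frame with per-generation `best` (best-so-far, nonincreasing) and
#'   `mean` population objective.
#' @export
ga_minimize <- function(objective, dim, config = ga_config()) {
  b <- expand_bounds(config$bounds, dim)
  width <- b[, 2] - b[, 1]
  sigma <- 0.1 * width
  withr::with_seed(config$seed, {
    np <- config$pop_size
    pop <- matrix(stats::runif(np * dim, b[, 1], b[, 2]), np, dim,
                  byrow = TRUE)
    fit <- penalize(apply(pop, 1, objective))
    best_i <- which.min(fit)
    best <- list(par = pop[best_i, ], value = fit[best_i])
    trace_best <- numeric(config$generations)
    trace_mean <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      tournament <- function() {
        ij <- sample.int(np, 2)
        pop[if (fit[ij[1]] <= fit[ij[2]]) ij[1] else ij[2], ]
      }
      newpop <- matrix(NA_real_, np, dim)
      newpop[1, ] <- best$par                       # elitism
      for (s in 2:np) {
        child <- if (stats::runif(1) < config$p_crossover) {
          u <- stats::runif(dim)
          u * tournament() + (1 - u) * tournament()
        } else {
          tournament()
        }
        mut <- stats::runif(dim) < config$p_mutation
        if (any(mut)) {
          child[mut] <- child[mut] + stats::rnorm(sum(mut)) * sigma[mut]
          child <- pmin(pmax(child, b[, 1]), b[, 2])
        }
        newpop[s, ] <- child
      }
      pop <- newpop
      fit <- penalize(apply(pop, 1, objective))
      gi <- which.min(fit)
      if (fit[gi] < best$value) best <- list(par = pop[gi, ], value = fit[gi])
      trace_best[g] <- best$value
      trace_mean[g] <- mean(fit)
    }
    list(par = best$par, value = best$value,
         trace = data.frame(generation = seq_len(config$generations),
                            best = trace_best, mean = trace_mean))
  })
}

#' Ant-colony-optimization configuration
#'
#' Continuous search by per-dimension candidate grids: each parameter is
#' discretized into `n_candidates_per_dim` equally spaced values over its
#' bounds and carries one pheromone entry per candidate. Defaults follow
#' the study's stated settings -- pheromone retention 0.9 after each
#' iteration (i.e. 10% evaporates), greedy-selection probability `q0 =
#' 0.2`, total pheromone normalized to 1 -- with the ant count and
#' iteration budget mirroring the genetic algorithm (30 and 50).
#' `retention` is deliberately a config field so the alternate reading of a
#' "volatilization coefficient" of 0.9 (retention 0.1) can be run as well.
#'
#' @param n_ants Ants per iteration.
#' @param iterations Iteration budget.
#' @param retention Fraction of pheromone kept per iteration, in (0, 1).
#' @param q0 Probability of greedy (argmax-pheromone) candidate choice,
#'   else roulette selection proportional to pheromone.
#' @param total_pheromone Total initial pheromone mass; deposits are
#'   normalized so the grand total stays at this value.
#' @param n_candidates_per_dim Grid resolution per dimension.
#' @param bounds Two-column matrix or length-2 vector, as in [ga_config()].
#' @param seed Integer seed.
#' @return A list of class `"aco_config"`.
#' @export
aco_config <- function(n_ants = 30, iterations = 50, retention = 0.9,
                       q0 = 0.2, total_pheromone = 1,
                       n_candidates_per_dim = 40, bounds = c(-3, 3),
                       seed = 1) {
  stopifnot(retention > 0, retention < 1, q0 >= 0, q0 <= 1,
            n_ants >= 1, iterations >= 1, n_candidates_per_dim >= 2,
            total_pheromone > 0)
  structure(list(n_ants = as.integer(n_ants),
                 iterations = as.integer(iterations), retention = retention,
                 q0 = q0, total_pheromone = total_pheromone,
                 n_candidates_per_dim = as.integer(n_candidates_per_dim),
                 bounds = bounds, seed = as.integer(seed)),
            class = "aco_config")
}

#' Minimize a function with grid-based continuous ant colony optimization
#'
#' Each ant assembles a solution by picking one grid candidate per
#' dimension: with probability `q0` the candidate with the most pheromone,
#' otherwise by pheromone-proportional roulette (uniform fallback for an
#' all-zero row). After every iteration the pheromone decays by the
#' retention factor and the iteration-best path receives a deposit sized so
#' the grand total stays at `total_pheromone`.
#'
#' @inheritParams ga_minimize
#' @param config An [aco_config()].
#' @param initial_pheromone Optional `dim x n_candidates_per_dim` matrix of
#'   nonnegative starting pheromone (normalized internally); defaults to
#'   uniform.
#' @return List with `par`, `value`, `trace` (per-iteration best-so-far and
#'   mean), `pheromone` (final matrix), `grid`, and `last_improved`, the
#'   iteration at which the best-so-far value last improved.
#' @export
aco_minimize <- function(objective, dim, config = aco_config(),
                         initial_pheromone = NULL) {
  b <- expand_bounds(config$bounds, dim)
  nc <- config$n_candidates_per_dim
  grid <- t(vapply(seq_len(dim),
                   function(j) seq(b[j, 1], b[j, 2], length.out = nc),
                   numeric(nc)))                      # dim x nc
  tau <- if (is.null(initial_pheromone)) {
    matrix(1, dim, nc)
  } else {
    stopifnot(all(dim(initial_pheromone) == c(dim, nc)),
              all(initial_pheromone >= 0))
    initial_pheromone
  }
  tau <- tau * (config$total_pheromone / sum(tau))
  deposit_total <- (1 - config$retention) * config$total_pheromone
  withr::with_seed(config$seed, {
    best <- list(par = NULL, value = Inf)
    last_improved <- 0L
    trace_best <- trace_mean <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      # candidate index per ant per dimension
      idx <- matrix(NA_integer_, config$n_ants, dim)
      for (j in seq_len(dim)) {
        row <- tau[j, ]
        prob <- if (sum(row) > 0) row / sum(row) else rep(1 / nc, nc)
        greedy <- which.max(row)
        g <- stats::runif(config$n_ants) < config$q0
        idx[, j] <- ifelse(g, greedy,
                           sample.int(nc, config$n_ants, replace = TRUE,
                                      prob = prob))
      }
      vals <- penalize(vapply(seq_len(config$n_ants), function(a) {
        objective(grid[cbind(seq_len(dim), idx[a, ])])
      }, numeric(1)))
      ib <- which.min(vals)
      if (vals[ib] < best$value) {
        best <- list(par = grid[cbind(seq_len(dim), idx[ib, ])],
                     value = vals[ib])
        last_improved <- it
      }
      tau <- tau * config$retention
      tau[cbind(seq_len(dim), idx[ib, ])] <-
        tau[cbind(seq_len(dim), idx[ib, ])] + deposit_total / dim
      trace_best[it] <- best$value
      trace_mean[it] <- mean(vals)
    }
    list(par = best$par, value = best$value,
         trace = data.frame(iteration = seq_len(config$iterations),
                            best = trace_best, mean = trace_mean),
         pheromone = tau, grid = grid, last_improved = last_improved)
  })
}

# training MSE (scaled space) of a flattened parameter vector
make_nn_objective <- function(xs, ys, h, n_in) {
  function(v) train_mse_scaled(unflatten_params(v, h, n_in), xs, ys)
}

#' Hybrid GA + backpropagation trainer
#'
#' Stage 1: the genetic algorithm searches the flattened weight/threshold
#' vector (length 25 for the 4-4-1 network) for the lowest training MSE.
#' Stage 2: backpropagation refines the GA's best vector. Refinement keeps
#' the best parameters seen, so the final training MSE never exceeds the
#' GA-stage MSE.
#'
#' @inheritParams train_bp
#' @param ga A [ga_config()]; its bounds apply to the scaled weight space.
#'   The trainer default of \[-1, 1\] keeps proposed weights in the
#'   responsive (unsaturated) range of the tanh units, where gradient
#'   refinement works well.
#' @param bp A [train_config()] for the refinement stage.
#' @return A `"bp_fit"` with an extra `report` element carrying
#'   `ga_value` (stage-1 MSE), `final_mse` and the GA `trace`.
#' @export
train_ga_bp <- function(data, h, ga = ga_config(bounds = c(-1, 1)),
                        bp = train_config()) {
  x <- as.matrix(data$x)
  y <- data$y
  scaler <- fit_scaler(x, y)
  xs <- scale_inputs(scaler, x)
  ys <- scale_response(scaler, y)
  obj <- make_nn_objective(xs, ys, h, ncol(x))
  stage1 <- ga_minimize(obj, n_params(h, ncol(x)), ga)
  fit <- train_bp(data, h, bp,
                  params0 = unflatten_params(stage1$par, h, ncol(x)),
                  scaler = scaler)
  fit$report <- list(ga_value = stage1$value, final_mse = fit$mse,
                     trace = stage1$trace)
  fit
}

#' Hybrid GA + ACO + backpropagation trainer
#'
#' Three stages. (1) A small genetic algorithm shapes the ant colony's
#' starting pheromone: it searches a bias value per candidate-grid column
#' (shared across parameter dimensions, mapped through `exp()` to a
#' positive pheromone profile), scoring each candidate profile by a short
#' ACO probe. (2) A full ACO run, started from the best profile, minimizes
#' the training MSE over the discretized weight space. (3) Backpropagation
#' refines the colony's best weights. Stage objectives are nonincreasing
#' from stage 2 to stage 3.
#'
#' @inheritParams train_ga_bp
#' @param ga Stage-1 [ga_config()]; because stage 1 only shapes a prior,
#'   its default budget here is reduced to population 10 and 10
#'   generations (probe: 10 ants, 5 iterations).
#' @param aco Stage-2 [aco_config()]; candidate grids default to \[-1, 1\]
#'   in scaled weight space for the same saturation reason as in
#'   [train_ga_bp()].
#' @return A `"bp_fit"` whose `report` lists `stage1_value`,
#'   `stage2_value`, `final_mse`, `aco_last_improved` and the stage traces.
#' @export
train_ga_aco_bp <- function(data, h,
                            ga = ga_config(pop_size = 10, generations = 10,
                                           bounds = c(-2, 2)),
                            aco = aco_config(bounds = c(-1, 1)),
                            bp = train_config()) {
  x <- as.matrix(data$x)
  y <- data$y
  scaler <- fit_scaler(x, y)
  xs <- scale_inputs(scaler, x)
  ys <- scale_response(scaler, y)
  npar <- n_params(h, ncol(x))
  obj <- make_nn_objective(xs, ys, h, ncol(x))
  nc <- aco$n_candidates_per_dim

  bias_to_tau <- function(bias) {
    matrix(exp(bias), npar, nc, byrow = TRUE)
  }
  probe_cfg <- aco
  probe_cfg$n_ants <- 10L
  probe_cfg$iterations <- 5L
  stage1 <- ga_minimize(function(bias) {
    aco_minimize(obj, npar, probe_cfg, initial_pheromone = bias_to_tau(bias))$value
  }, dim = nc, config = ga)

  stage2 <- aco_minimize(obj, npar, aco,
                         initial_pheromone = bias_to_tau(stage1$par))
  fit <- train_bp(data, h, bp,
                  params0 = unflatten_params(stage2$par, h, ncol(x)),
                  scaler = scaler)
  fit$report <- list(stage1_value = stage1$value, stage2_value = stage2$value,
                     final_mse = fit$mse,
                     aco_last_improved = stage2$last_improved,
                     ga_trace = stage1$trace, aco_trace = stage2$trace)
  fit
}
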