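#' Candidate hidden-layer sizes
#'
#' The usual rule of thumb for a single hidden layer: `round(sqrt(m + n)) +
#' a` for `a = 1..10`, where m and n are the input and output widths. For
#' the 4-input, 1-output extraction surrogate this gives candidates 3..12;
#' the study settled on 4 by comparing training-set MSE.
#'
#' @param n_in,n_out Input and output layer sizes.
#' @return Ascending integer vector of at most 10 candidates.
#' @export
hidden_candidates <- function(n_in, n_out) {
  stopifnot(n_in >= 1, n_out >= 1)
  sort(unique(round(sqrt(n_in + n_out)) + 1:10))
}

#' Min-max scaler to [-1, 1]
#'
#' Fitted on training data only; transforms each input column and the
#' response linearly onto \[-1, 1\] over the training range and back. A
#' degenerate (constant) column is mapped to 0.
#'
#' @param x Numeric input matrix (rows are samples).
#' @param y Numeric response vector.
#' @return An object of class `"minmax_scaler"`.
#' @export
fit_scaler <- function(x, y) {
  x <- as.matrix(x)
  structure(list(x_min = apply(x, 2, min), x_max = apply(x, 2, max),
                 y_min = min(y), y_max = max(y)),
            class = "minmax_scaler")
}

scale01 <- function(v, lo, hi) {
  if (hi - lo <= 0) return(rep(0, length(v)))
  2 * (v - lo) / (hi - lo) - 1
}

#' @rdname fit_scaler
#' @param scaler A fitted `"minmax_scaler"`.
#' @export
scale_inputs <- function(scaler, x) {
  check_scaler(scaler)
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  for (j in seq_len(ncol(x))) {
    x[, j] <- scale01(x[, j], scaler$x_min[j], scaler$x_max[j])
  }
  x
}

#' @rdname fit_scaler
#' @export
scale_response <- function(scaler, y) {
  check_scaler(scaler)
  scale01(y, scaler$y_min, scaler$y_max)
}

#' @rdname fit_scaler
#' @param ys Response values on the scaled [-1, 1] scale.
#' @export
unscale_response <- function(scaler, ys) {
  check_scaler(scaler)
  if (scaler$y_max - scaler$y_min <= 0) return(rep(scaler$y_min, length(ys)))
  (ys + 1) / 2 * (scaler$y_max - scaler$y_min) + scaler$y_min
}

check_scaler <- function(scaler) {
  if (!inherits(scaler, "minmax_scaler")) {
    stop("state error: scaler has not been fitted (see fit_scaler)")
  }
  invisible(TRUE)
}

#' Feedforward network parameters
#'
#' Weights and thresholds (biases) of a single-hidden-layer regressor with
#' tanh hidden activation and linear output. The full parameter set
#' flattens losslessly to a vector of length
#' `n_hidden * (n_in + 1) + n_out * (n_hidden + 1)` (25 for the 4-4-1
#' network), which is the encoding the metaheuristic trainers search over.
#'
#' @param n_hidden Hidden-layer width.
#' @param n_in,n_out Input/output widths (default 4 and 1).
#' @param w1 `n_hidden x n_in` input-to-hidden weights.
#' @param b1 Length-`n_hidden` hidden thresholds.
#' @param w2 `n_out x n_hidden` hidden-to-output weights.
#' @param b2 Length-`n_out` output thresholds.
#' @return An object of class `"network_params"`.
#' @export
network_params <- function(n_hidden, n_in = 4, n_out = 1,
                           w1 = matrix(0, n_hidden, n_in),
                           b1 = numeric(n_hidden),
                           w2 = matrix(0, n_out, n_hidden),
                           b2 = numeric(n_out)) {
  stopifnot(nrow(w1) == n_hidden, ncol(w1) == n_in, length(b1) == n_hidden,
            nrow(w2) == n_out, ncol(w2) == n_hidden, length(b2) == n_out)
  structure(list(n_in = n_in, n_hidden = n_hidden, n_out = n_out,
                 w1 = w1, b1 = b1, w2 = w2, b2 = b2),
            class = "network_params")
}

#' @rdname network_params
#' @param params A `"network_params"`.
#' @export
flatten_params <- function(params) {
  c(as.vector(params$w1), params$b1, as.vector(params$w2), params$b2)
}

#' @rdname network_params
#' @param v Flat parameter vector of the matching length.
#' @export
unflatten_params <- function(v, n_hidden, n_in = 4, n_out = 1) {
  expect <- n_hidden * (n_in + 1) + n_out * (n_hidden + 1)
  if (length(v) != expect) {
    stop("parameter vector has length ", length(v), ", expected ", expect)
  }
  i <- 0
  take <- function(m) {
    out <- v[i + seq_len(m)]
    i <<- i + m
    out
  }
  network_params(n_hidden, n_in, n_out,
                 w1 = matrix(take(n_hidden * n_in), n_hidden, n_in),
                 b1 = take(n_hidden),
                 w2 = matrix(take(n_out * n_hidden), n_out, n_hidden),
                 b2 = take(n_out))
}

#' @rdname network_params
#' @export
n_params <- function(n_hidden, n_in = 4, n_out = 1) {
  n_hidden * (n_in + 1) + n_out * (n_hidden + 1)
}

# forward pass on already-scaled inputs; returns scaled outputs (n x n_out)
nn_forward_scaled <- function(params, xs) {
  xs <- if (is.null(dim(xs))) matrix(xs, nrow = 1) else xs
  h <- tanh(xs %*% t(params$w1) + rep(params$b1, each = nrow(xs)))
  h %*% t(params$w2) + rep(params$b2, each = nrow(xs))
}

#' Evaluate the network on actual-unit inputs
#'
#' Inputs are min-max scaled, pushed through the tanh hidden layer and the
#' linear output, and the output is inverse-scaled back to percent yield.
#' Pass `scaler = NULL` to operate directly on the network's internal
#' scale (identity scaling).
#'
#' @param params A `"network_params"`.
#' @param x Input vector (one sample) or matrix (rows are samples) in
#'   actual units.
#' @param scaler A fitted `"minmax_scaler"`, or `NULL` for identity.
#' @return Numeric vector of predictions in response units.
#' @export
nn_forward <- function(params, x, scaler = NULL) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (!is.null(scaler)) x <- scale_inputs(scaler, x)
  out <- nn_forward_scaled(params, x)
  if (!is.null(scaler)) out <- unscale_response(scaler, drop(out))
  drop(out)
}

train_mse_scaled <- function(params, xs, ys) {
  mean((drop(nn_forward_scaled(params, xs)) - ys)^2)
}

#' Backpropagation training configuration
#'
#' Defaults follow the study's stated stopping rule: at most 1000 epochs,
#' stop early when the training MSE (on the scaled data) drops below 1e-5.
#' The learning rate applies to plain batch gradient descent; the default
#' of 0.5 is calibrated to the package's primary problem geometry (a 4-h-1
#' tanh regressor on data min-max scaled to \[-1, 1\]) -- smoother,
#' lower-curvature targets converge more cleanly with smaller rates.
#'
#' @param max_epochs Maximum number of epochs (>= 1).
#' @param goal_mse Target training MSE (> 0).
#' @param learning_rate Gradient-descent step size.
#' @param seed Integer seed for the weight initialization.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(max_epochs = 1000, goal_mse = 1e-5,
                         learning_rate = 0.5, seed = 1) {
  stopifnot(max_epochs >= 1, goal_mse > 0, learning_rate > 0)
  structure(list(max_epochs = as.integer(max_epochs), goal_mse = goal_mse,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

#' Train the regressor by batch backpropagation
#'
#' Full-batch gradient descent on the mean squared error of the scaled
#' training data. Weights are initialized uniformly on (-0.5, 0.5) from the
#' seeded generator (unless `params0` supplies a starting point, as the
#' hybrid trainers do). The parameters with the lowest training MSE seen
#' during the run are returned, so the final training error never exceeds
#' the initial one.
#'
#' @param data List with `x` (n x n_in matrix, actual units) and `y`
#'   (length-n response vector).
#' @param h Hidden-layer width.
#' @param config A [train_config()].
#' @param params0 Optional `"network_params"` starting point.
#' @param scaler Optional pre-fitted scaler; defaults to fitting on `data`.
#' @return List of class `"bp_fit"`: `params`, `scaler`, `history` (epoch
#'   MSE trace, element 1 is the pre-training MSE), `mse` (best training
#'   MSE, scaled space), `h`, `epochs_run`.
#' @export
train_bp <- function(data, h, config = train_config(), params0 = NULL,
                     scaler = NULL) {
  x <- as.matrix(data$x)
  y <- data$y
  stopifnot(nrow(x) >= 2, h >= 1, length(y) == nrow(x))
  if (is.null(scaler)) scaler <- fit_scaler(x, y)
  xs <- scale_inputs(scaler, x)
  ys <- scale_response(scaler, y)
  n_in <- ncol(x)
  params <- if (is.null(params0)) {
    withr::with_seed(config$seed, unflatten_params(
      stats::runif(n_params(h, n_in), -0.5, 0.5), h, n_in))
  } else {
    params0
  }
  n <- nrow(xs)
  lr <- config$learning_rate
  mse0 <- train_mse_scaled(params, xs, ys)
  history <- numeric(config$max_epochs + 1)
  history[1] <- mse0
  best <- list(params = params, mse = mse0)
  epochs <- 0L
  for (e in seq_len(config$max_epochs)) {
    hid <- tanh(xs %*% t(params$w1) + rep(params$b1, each = n))   # n x h
    out <- drop(hid %*% t(params$w2)) + params$b2                 # n
    err <- out - ys
    if (!all(is.finite(err)) || !is.finite(mean(err^2))) {
      stop("divergence error: non-finite loss at epoch ", e,
           "; try a smaller learning rate")
    }
    g_out <- 2 * err / n                                          # n
    g_w2 <- matrix(crossprod(g_out, hid), nrow = 1)               # 1 x h
    g_b2 <- sum(g_out)
    g_hid <- outer(g_out, drop(params$w2)) * (1 - hid^2)          # n x h
    g_w1 <- t(g_hid) %*% xs                                       # h x n_in
    g_b1 <- colSums(g_hid)
    params$w1 <- params$w1 - lr * g_w1
    params$b1 <- params$b1 - lr * g_b1
    params$w2 <- params$w2 - lr * g_w2
    params$b2 <- params$b2 - lr * g_b2
    m <- train_mse_scaled(params, xs, ys)
    if (!is.finite(m)) {
      stop("divergence error: non-finite loss at epoch ", e,
           "; try a smaller learning rate")
    }
    history[e + 1] <- m
    epochs <- e
    if (m < best$mse) best <- list(params = params, mse = m)
    if (m < config$goal_mse) break
  }
  structure(list(params = best$params, scaler = scaler,
                 history = history[seq_len(epochs + 1)], mse = best$mse,
                 h = h, epochs_run = epochs),
            class = "bp_fit")
}

#' @export
print.bp_fit <- function(x, ...) {
  cat(sprintf("BP fit: %d-%d-%d network, %d epoch(s), train MSE %.3g (scaled)\n",
              x$params$n_in, x$h, x$params$n_out, x$epochs_run, x$mse))
  invisible(x)
}

#' Predict from a trained fit
#' @param object A `"bp_fit"`.
#' @param x Inputs in actual units.
#' @param ... Unused.
#' @export
predict.bp_fit <- function(object, x, ...) {
  nn_forward(object$params, x, object$scaler)
}

#' Pick the hidden-layer width by training-set MSE
#'
#' Trains one network per candidate width (see [hidden_candidates()]) under
#' the same configuration and returns the width with the lowest final
#' training MSE; ties go to the smaller network.
#'
#' @inheritParams train_bp
#' @param candidates Integer vector of widths to try.
#' @return The selected width (integer), with the per-candidate MSEs in
#'   attribute `"mse"`.
#' @export
select_hidden_size <- function(data, config = train_config(),
                               candidates = hidden_candidates(ncol(as.matrix(data$x)), 1)) {
  stopifnot(length(candidates) >= 1)
  mses <- vapply(candidates,
                 function(h) train_bp(data, h, config)$mse, numeric(1))
  best <- candidates[which.min(mses)]  # which.min takes the first ⇒ smallest h on ties
  structure(best, mse = stats::setNames(mses, candidates))
}
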