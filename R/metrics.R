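#' Prediction-accuracy metrics
#'
#' Mean absolute error, root mean square error and the coefficient of
#' determination `R2 = 1 - RSS/TSS`, the three quantities used to compare
#' the response-surface and neural-network surrogates. `r_squared()` can be
#' negative (a model worse than the mean) and is undefined for a constant
#' actual vector.
#'
#' @param actual Numeric vector of measured responses.
#' @param predicted Numeric vector of model predictions, same length.
#' @return A single number.
#' @examples
#' mae(c(1, 2), c(2, 2))     # 0.5
#' rmse(c(0, 0), c(1, -1))   # 1
#' @export
mae <- function(actual, predicted) {
  check_paired(actual, predicted)
  mean(abs(actual - predicted))
}

#' @rdname mae
#' @export
rmse <- function(actual, predicted) {
  check_paired(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' @rdname mae
#' @export
r_squared <- function(actual, predicted) {
  check_paired(actual, predicted)
  tss <- sum((actual - mean(actual))^2)
  if (tss <= 0) stop("r_squared undefined: actual values are constant")
  1 - sum((actual - predicted)^2) / tss
}

check_paired <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("length mismatch: actual has ", length(actual), ", predicted has ",
         length(predicted))
  }
  if (length(actual) == 0L) stop("empty input")
  invisible(TRUE)
}

#' Compare the four published models on the 29-run experiment
#'
#' Computes R-squared, MAE and RMSE for each stored prediction column
#' against the measured yields. The published comparison table was computed
#' over all 29 runs (training rows included), so that is the default basis.
#'
#' @param fixture A [prac_fixture()] (or compatible list with `design` and
#'   `predicted`).
#' @param basis `"all"` (default) or `"subset"`; with `"subset"`, `rows`
#'   selects the runs.
#' @param rows Integer run indices when `basis = "subset"`.
#' @return Data frame with columns `model`, `r2`, `mae`, `rmse`, `n`.
#' @export
compare_models <- function(fixture, basis = c("all", "subset"), rows = NULL) {
  basis <- match.arg(basis)
  y <- fixture$design$runs$response
  idx <- if (basis == "all") seq_along(y) else sort(rows)
  out <- do.call(rbind, lapply(names(fixture$predicted), function(m) {
    p <- fixture$predicted[[m]]
    data.frame(model = m,
               r2 = r_squared(y[idx], p[idx]),
               mae = mae(y[idx], p[idx]),
               rmse = rmse(y[idx], p[idx]),
               n = length(idx))
  }))
  rownames(out) <- NULL
  out
}

#' Seeded train/test split of a design table
#'
#' Uniform split without replacement, reproducible under the seed; the
#' study used 21 training and 8 test runs out of 29.
#'
#' @param design A [design_table()].
#' @param n_train Number of training runs (must be `< n`).
#' @param seed Integer seed.
#' @return List with `train` and `test` design tables and the integer row
#'   indices `train_idx`, `test_idx`.
#' @export
split_design <- function(design, n_train, seed) {
  n <- nrow(design$runs)
  if (n_train >= n) stop("n_train must be smaller than the number of runs")
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  idx <- sort(idx)
  subset_design <- function(i) {
    design_table(design$factors, design_settings(design)[i, , drop = FALSE],
                 response = design$runs$response[i], run = design$runs$run[i])
  }
  list(train = subset_design(idx), test = subset_design(setdiff(seq_len(n), idx)),
       train_idx = idx, test_idx = setdiff(seq_len(n), idx))
}
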