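#' Full second-order polynomial model
#'
#' Container for a response-surface model in k factors: intercept, k linear
#' terms, all k(k-1)/2 two-way interactions (pair order (1,2), (1,3), ...,
#' (k-1,k)) and k pure-quadratic terms. Coefficients live either in actual
#' units or in -1/0/+1 coded units; [convert_units()] moves between the two
#' exactly.
#'
#' @param intercept Intercept.
#' @param linear Numeric k-vector of linear coefficients.
#' @param interaction Numeric k(k-1)/2-vector of interaction coefficients in
#'   pair-lexicographic order.
#' @param quadratic Numeric k-vector of squared-term coefficients.
#' @param units `"actual"` or `"coded"`.
#' @param factors Factor data frame (see [factor_spec()]); carries the level
#'   information needed for unit conversion and prediction.
#' @return An object of class `"quadratic_model"`.
#' @export
quadratic_model <- function(intercept, linear, interaction, quadratic,
                            units = c("actual", "coded"), factors) {
  units <- match.arg(units)
  k <- nrow(factors)
  stopifnot(length(linear) == k, length(quadratic) == k,
            length(interaction) == k * (k - 1) / 2)
  coef <- c(intercept, linear, interaction, quadratic)
  names(coef) <- quad_term_names(factors$name)
  structure(list(coef = coef, units = units, factors = factors, k = k),
            class = "quadratic_model")
}

quad_term_names <- function(fnames) {
  k <- length(fnames)
  pairs <- utils::combn(k, 2)
  c("(Intercept)", fnames,
    apply(pairs, 2, function(ij) paste(fnames[ij], collapse = ":")),
    paste0(fnames, "^2"))
}

#' Second-order model matrix
#'
#' Expands a settings matrix into the 1 + k + k(k-1)/2 + k column basis of
#' the full quadratic: intercept, linear, pairwise products, squares.
#'
#' @param settings Numeric matrix (runs by factors) or vector (one run).
#' @param fnames Optional factor names for labelling.
#' @return Numeric matrix with one column per model term.
#' @export
quad_model_matrix <- function(settings, fnames = NULL) {
  x <- if (is.null(dim(settings))) matrix(settings, nrow = 1) else as.matrix(settings)
  k <- ncol(x)
  if (is.null(fnames)) fnames <- colnames(x)
  if (is.null(fnames)) fnames <- paste0("x", seq_len(k))
  pairs <- utils::combn(k, 2)
  inter <- apply(pairs, 2, function(ij) x[, ij[1]] * x[, ij[2]])
  if (nrow(x) == 1L) inter <- matrix(inter, nrow = 1)
  mm <- cbind(1, x, inter, x^2)
  colnames(mm) <- quad_term_names(fnames)
  mm
}

#' Fit the full quadratic response surface by least squares
#'
#' Ordinary least squares over the full second-order basis. Fitted values
#' and residual sums of squares are identical whichever unit system is
#' requested; only the coefficient parameterization changes.
#'
#' @param design A [design_table()] with measured responses.
#' @param units Coefficient units of the returned model, `"actual"`
#'   (default) or `"coded"`.
#' @return A `"quadratic_model"`.
#' @export
fit_quadratic <- function(design, units = c("actual", "coded")) {
  units <- match.arg(units)
  y <- design$runs$response
  if (anyNA(y)) stop("design has missing responses; cannot fit")
  k <- nrow(design$factors)
  p <- 1 + 2 * k + k * (k - 1) / 2
  if (length(y) < p) {
    stop("need at least ", p, " runs to fit the full quadratic in ", k,
         " factors; have ", length(y))
  }
  s <- design_settings(design)
  if (units == "coded") s <- code_settings(s, design$factors)
  mm <- quad_model_matrix(s, design$factors$name)
  fit <- stats::lm.fit(mm, y)
  if (fit$rank < ncol(mm)) {
    aliased <- colnames(mm)[is.na(fit$coefficients)]
    stop("singular design: collinear term(s) ",
         paste(aliased, collapse = ", "))
  }
  co <- fit$coefficients
  npair <- k * (k - 1) / 2
  quadratic_model(co[1], co[1 + seq_len(k)], co[1 + k + seq_len(npair)],
                  co[1 + k + npair + seq_len(k)],
                  units = units, factors = design$factors)
}

#' Evaluate a quadratic model
#'
#' @param object A `"quadratic_model"`.
#' @param settings Factor settings in the model's own unit system: a vector
#'   (one point) or a matrix (one row per point).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.quadratic_model <- function(object, settings, ...) {
  mm <- quad_model_matrix(settings, object$factors$name)
  drop(mm %*% object$coef)
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat("Second-order response-surface model (", x$units, " units, ",
      x$k, " factors)\n", sep = "")
  print(signif(x$coef, 6))
  invisible(x)
}

#' Convert a quadratic model between actual and coded units
#'
#' Exact algebraic reparameterization: writing the polynomial as
#' a0 + b'x + x'Qx and substituting the affine coding x = m + S c gives the
#' coded-unit coefficients in closed form (and conversely). Round-tripping
#' reproduces the original coefficients to machine precision.
#'
#' @param model A `"quadratic_model"`.
#' @param to Target units, `"actual"` or `"coded"`.
#' @return A `"quadratic_model"` in the requested units.
#' @export
convert_units <- function(model, to = c("actual", "coded")) {
  to <- match.arg(to)
  if (identical(model$units, to)) return(model)
  k <- model$k
  npair <- k * (k - 1) / 2
  co <- model$coef
  a0 <- co[1]
  b <- co[1 + seq_len(k)]
  bij <- co[1 + k + seq_len(npair)]
  bii <- co[1 + k + npair + seq_len(k)]
  Q <- diag(bii, k)
  pairs <- utils::combn(k, 2)
  for (t in seq_len(npair)) {
    i <- pairs[1, t]; j <- pairs[2, t]
    Q[i, j] <- Q[j, i] <- bij[t] / 2
  }
  m <- model$factors$center
  s <- (model$factors$high - model$factors$low) / 2
  if (to == "coded") {
    # x = m + S c
    S <- diag(s, k)
    a0n <- a0 + sum(b * m) + drop(t(m) %*% Q %*% m)
    bn <- drop(S %*% (b + 2 * Q %*% m))
    Qn <- S %*% Q %*% S
  } else {
    # c = S^{-1} (x - m)
    Sinv <- diag(1 / s, k)
    Qn <- Sinv %*% Q %*% Sinv
    bn <- drop(Sinv %*% b) - drop(2 * Qn %*% m)
    a0n <- a0 - sum(drop(Sinv %*% b) * m) + drop(t(m) %*% Qn %*% m)
  }
  inter <- apply(pairs, 2, function(ij) 2 * Qn[ij[1], ij[2]])
  quadratic_model(a0n, bn, inter, diag(Qn), units = to,
                  factors = model$factors)
}

#' ANOVA for a fitted Box-Behnken quadratic
#'
#' Design-Expert-style analysis of variance of the full second-order model:
#' partial (Type-III) sums of squares per term computed in coded units
#' (where the three-level design is orthogonal for linear and interaction
#' terms), F = MS(term)/MS(Residual), lack of fit tested against pure error
#' estimated from replicate groups, and the usual summary quantities
#' (R-squared family, PRESS, CV%).
#'
#' @param model A fitted `"quadratic_model"` (either unit system).
#' @param design The [design_table()] the model was fitted on.
#' @return An object of class `"bbd_anova"`: list with `table` (data frame
#'   with columns source, ss, df, ms, f, p), `r2`, `adj_r2`, `pred_r2`,
#'   `press`, `cv_percent`, and `pure_error_available`.
#' @export
quad_anova <- function(model, design) {
  y <- design$runs$response
  n <- length(y)
  k <- nrow(design$factors)
  coded <- code_settings(design_settings(design), design$factors)
  mm <- quad_model_matrix(coded, design$factors$name)
  p <- ncol(mm)
  fit <- stats::lm.fit(mm, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  ss_model <- tss - rss
  df_model <- p - 1
  df_res <- n - p
  ms_res <- rss / df_res
  # partial SS: increase in RSS when one column is dropped
  terms <- colnames(mm)[-1]
  ss_term <- vapply(seq_along(terms), function(j) {
    sub <- stats::lm.fit(mm[, -(j + 1), drop = FALSE], y)
    sum(sub$residuals^2) - rss
  }, numeric(1))
  names(ss_term) <- terms

  # pure error from replicate groups (runs with identical settings)
  key <- apply(coded, 1, paste, collapse = "/")
  reps <- split(y, key)
  ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
  df_pe <- n - length(reps)
  pure_error_available <- df_pe > 0
  if (!pure_error_available) {
    warning("no replicate runs: pure error undefined, lack-of-fit test omitted")
  }
  ss_lof <- rss - ss_pe
  df_lof <- df_res - df_pe

  press <- tryCatch(press_stats(design),
                    error = function(e) list(press = NA_real_,
                                             pred_r2 = NA_real_))
  f_model <- (ss_model / df_model) / ms_res
  rows <- list(
    c("Model", ss_model, df_model, ss_model / df_model, f_model,
      stats::pf(f_model, df_model, df_res, lower.tail = FALSE))
  )
  for (t in terms) {
    f <- ss_term[[t]] / ms_res
    rows[[length(rows) + 1]] <- c(t, ss_term[[t]], 1, ss_term[[t]], f,
                                  stats::pf(f, 1, df_res, lower.tail = FALSE))
  }
  rows[[length(rows) + 1]] <- c("Residual", rss, df_res, ms_res, NA, NA)
  if (pure_error_available) {
    f_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
    rows[[length(rows) + 1]] <-
      c("Lack of Fit", ss_lof, df_lof, ss_lof / df_lof, f_lof,
        stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE))
    rows[[length(rows) + 1]] <- c("Pure Error", ss_pe, df_pe, ss_pe / df_pe,
                                  NA, NA)
  }
  rows[[length(rows) + 1]] <- c("Cor Total", tss, n - 1, NA, NA, NA)
  tab <- data.frame(
    source = vapply(rows, `[[`, character(1), 1),
    ss = as.numeric(vapply(rows, `[[`, character(1), 2)),
    df = as.integer(as.numeric(vapply(rows, `[[`, character(1), 3))),
    ms = as.numeric(vapply(rows, `[[`, character(1), 4)),
    f = as.numeric(vapply(rows, `[[`, character(1), 5)),
    p = as.numeric(vapply(rows, `[[`, character(1), 6))
  )
  structure(list(
    table = tab,
    r2 = 1 - rss / tss,
    adj_r2 = 1 - (rss / df_res) / (tss / (n - 1)),
    press = press$press,
    pred_r2 = press$pred_r2,
    cv_percent = 100 * sqrt(ms_res) / mean(y),
    pure_error_available = pure_error_available
  ), class = "bbd_anova")
}

#' @export
print.bbd_anova <- function(x, digits = 4, ...) {
  tab <- x$table
  tab$p <- ifelse(!is.na(tab$p) & tab$p < 1e-4, "<0.0001",
                  format(round(tab$p, 4)))
  print(cbind(tab["source"],
              round(tab[c("ss", "ms", "f")], digits),
              tab[c("df", "p")])[, c("source", "ss", "df", "ms", "f", "p")],
        row.names = FALSE, ...)
  cat(sprintf("R2 %.4f | adj R2 %.4f | pred R2 %.4f | PRESS %.4f | CV%% %.2f\n",
              x$r2, x$adj_r2, x$pred_r2, x$press, x$cv_percent))
  invisible(x)
}

#' PRESS and predicted R-squared
#'
#' Leave-one-out prediction error sum of squares via the hat-matrix identity
#' `e_i / (1 - h_ii)` (no refits), and the derived cross-validated
#' R-squared `1 - PRESS / SS(total)`.
#'
#' @param design A [design_table()] with responses.
#' @return List with `press`, `pred_r2` and the per-run leverages `h`.
#' @export
press_stats <- function(design) {
  y <- design$runs$response
  coded <- code_settings(design_settings(design), design$factors)
  mm <- quad_model_matrix(coded, design$factors$name)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) stop("singular design: PRESS undefined")
  h <- rowSums(qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]^2)
  res <- stats::lm.fit(mm, y)$residuals
  if (any(1 - h < 1e-10)) {
    stop("leverage of 1 for run(s) ",
         paste(design$runs$run[1 - h < 1e-10], collapse = ", "),
         ": PRESS undefined")
  }
  press <- sum((res / (1 - h))^2)
  tss <- sum((y - mean(y))^2)
  list(press = press, pred_r2 = 1 - press / tss, h = h)
}

#' Maximize a fitted quadratic over a box
#'
#' Multi-start bounded quasi-Newton search (L-BFGS-B from every corner of
#' the box plus its center); a quadratic over a box can attain its maximum
#' on the boundary, which the corner starts cover. Ties within `1e-8` of
#' the best value are broken toward the lexicographically smallest
#' settings.
#'
#' @param model A `"quadratic_model"`.
#' @param bounds Two-column matrix (low, high) per factor, in the model's
#'   unit system; defaults to each factor's low/high levels (or -1/+1 for a
#'   coded model).
#' @return List with `settings` (the maximizer), `value` and `bounds`.
#' @export
optimize_surface <- function(model, bounds = NULL) {
  k <- model$k
  if (is.null(bounds)) {
    bounds <- if (model$units == "coded") {
      cbind(rep(-1, k), rep(1, k))
    } else {
      cbind(model$factors$low, model$factors$high)
    }
  }
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == k, all(is.finite(bounds)),
            all(bounds[, 1] <= bounds[, 2]))
  obj <- function(x) -predict(model, x)
  grad <- function(x) {
    co <- model$coef
    b <- co[1 + seq_len(k)]
    npair <- k * (k - 1) / 2
    bij <- co[1 + k + seq_len(npair)]
    bii <- co[1 + k + npair + seq_len(k)]
    g <- b + 2 * bii * x
    pairs <- utils::combn(k, 2)
    for (t in seq_len(npair)) {
      i <- pairs[1, t]; j <- pairs[2, t]
      g[i] <- g[i] + bij[t] * x[j]
      g[j] <- g[j] + bij[t] * x[i]
    }
    -g
  }
  corners <- as.matrix(expand.grid(lapply(seq_len(k), function(j) bounds[j, ])))
  starts <- rbind(corners, matrix(rowMeans(bounds), nrow = 1))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- stats::optim(starts[i, ], obj, grad, method = "L-BFGS-B",
                        lower = bounds[, 1], upper = bounds[, 2],
                        control = list(factr = 1, maxit = 500))
    cand <- list(settings = unname(res$par), value = -res$value)
    if (is.null(best) || cand$value > best$value + 1e-8 ||
        (abs(cand$value - best$value) <= 1e-8 &&
         lex_less(cand$settings, best$settings))) {
      best <- cand
    }
  }
  names(best$settings) <- model$factors$name
  c(best, list(bounds = bounds))
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}
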