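#' Closed-form assay formulas
#'
#' The gravimetric and spectrophotometric bookkeeping used around the
#' extraction and liposome work, all returning percentages except `ke`:
#' * `yield_pct(w_raw, w_poly)`: extraction yield, polysaccharide mass over
#'   raw-material mass x 100.
#' * `purity_pct(w_poly, w_sugar)`: sugar mass (phenol-sulfuric assay) over
#'   crude polysaccharide mass x 100.
#' * `ee_pct(w_free, w_total)`: encapsulation efficiency, entrapped over
#'   total polysaccharide x 100.
#' * `lc_pct(w_free, w_total, w_carrier)`: loading capacity, entrapped
#'   polysaccharide over (carrier + total polysaccharide) mass x 100.
#' * `stability_ke(a0, a)`: stability coefficient, relative absorbance drop
#'   after centrifugation (0 = no loss).
#'
#' @param w_raw,w_poly,w_sugar,w_free,w_total,w_carrier Masses (>= 0; any
#'   consistent unit).
#' @param a0,a Absorbance before/after centrifugation.
#' @return A number (vectorized over inputs).
#' @examples
#' ee_pct(0, 10)          # 100: nothing free
#' lc_pct(3, 10, 790)     # 0.875
#' stability_ke(0.8, 0.8) # 0
#' @name assay_formulas
NULL

check_pos <- function(x, what) {
  if (any(x <= 0)) stop("domain error: ", what, " must be > 0")
  invisible(TRUE)
}
check_nonneg <- function(x, what) {
  if (any(x < 0)) stop("domain error: ", what, " must be >= 0")
  invisible(TRUE)
}

#' @rdname assay_formulas
#' @export
yield_pct <- function(w_raw, w_poly) {
  check_pos(w_raw, "raw-material mass"); check_nonneg(w_poly, "polysaccharide mass")
  w_poly / w_raw * 100
}

#' @rdname assay_formulas
#' @export
purity_pct <- function(w_poly, w_sugar) {
  check_pos(w_poly, "polysaccharide mass"); check_nonneg(w_sugar, "sugar mass")
  w_sugar / w_poly * 100
}

#' @rdname assay_formulas
#' @export
ee_pct <- function(w_free, w_total) {
  check_pos(w_total, "total polysaccharide mass")
  check_nonneg(w_free, "free polysaccharide mass")
  (w_total - w_free) / w_total * 100
}

#' @rdname assay_formulas
#' @export
lc_pct <- function(w_free, w_total, w_carrier) {
  check_nonneg(w_free, "free polysaccharide mass")
  check_nonneg(w_carrier, "carrier mass")
  check_pos(w_carrier + w_total, "carrier + total mass")
  (w_total - w_free) / (w_carrier + w_total) * 100
}

#' @rdname assay_formulas
#' @export
stability_ke <- function(a0, a) {
  check_pos(a0, "pre-centrifugation absorbance")
  (a0 - a) / a0
}

#' First-order release model
#'
#' Cumulative release `M(t) = m_inf * (1 - exp(-k t))`: monotone
#' nondecreasing from 0 at t = 0 toward the plateau `m_inf` (% released),
#' with rate constant `k` per hour. The in-vitro liposome release curves
#' followed this law at both gastric and intestinal pH.
#'
#' @param m_inf Plateau cumulative release, in (0, 100\].
#' @param k Rate constant (> 0), per hour.
#' @param r2 Optional goodness of fit stored with the model.
#' @return A list of class `"release_model"`.
#' @export
release_model <- function(m_inf, k, r2 = NA_real_) {
  stopifnot(m_inf > 0, m_inf <= 100, k > 0)
  structure(list(m_inf = m_inf, k = k, r2 = r2), class = "release_model")
}

#' @export
print.release_model <- function(x, ...) {
  cat(sprintf("First-order release: M(t) = %.4g * (1 - exp(-%.4g t))",
              x$m_inf, x$k))
  if (!is.na(x$r2)) cat(sprintf("  [R2 = %.4f]", x$r2))
  cat("\n")
  invisible(x)
}

#' Evaluate the release curve
#'
#' @param model A [release_model()].
#' @param t Time(s) in hours (>= 0).
#' @return Cumulative release in percent.
#' @export
release_curve <- function(model, t) {
  stopifnot(all(t >= 0))
  model$m_inf * (1 - exp(-model$k * t))
}

#' Fit the first-order release model
#'
#' Nonlinear least squares (Levenberg-Marquardt) for the plateau and rate.
#' Starting values: the observed maximum for the plateau and the log-slope
#' of the earliest positive-time point for the rate. When the data are not
#' predominantly increasing, the fit is still returned but flagged with a
#' warning.
#'
#' @param times Sampling times in hours (>= 3 points, beginning at or near
#'   zero).
#' @param cumrel Cumulative release (%) at those times.
#' @return A [release_model()] with the achieved `r2`.
#' @export
fit_release <- function(times, cumrel) {
  stopifnot(length(times) == length(cumrel), length(times) >= 3,
            min(times) <= 1)
  if (mean(diff(cumrel[order(times)]) < 0) > 0.5) {
    warning("quality warning: release data are predominantly decreasing")
  }
  m0 <- max(cumrel)
  i1 <- which(times > 0)[which.min(times[times > 0])]
  frac <- min(0.999, max(1e-6, cumrel[i1] / max(m0, 1e-9)))
  k0 <- max(0.01, -log(1 - frac) / times[i1])
  df <- data.frame(t = times, m = cumrel)
  fit <- tryCatch(
    minpack.lm::nlsLM(m ~ minf * (1 - exp(-k * t)), data = df,
                      start = list(minf = m0, k = k0),
                      lower = c(1e-6, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    pred <- stats::predict(fit)
  } else {
    # ill-conditioned data (e.g. decreasing curves): direct least squares
    # on log-parameters, which cannot fail structurally
    sse <- function(lp) {
      sum((cumrel - exp(lp[1]) * (1 - exp(-exp(lp[2]) * times)))^2)
    }
    op <- stats::optim(log(c(max(m0, 1e-3), k0)), sse,
                       method = "Nelder-Mead")
    est <- c(minf = exp(op$par[1]), k = exp(op$par[2]))
    pred <- est[["minf"]] * (1 - exp(-est[["k"]] * times))
  }
  tss <- sum((cumrel - mean(cumrel))^2)
  r2 <- if (tss > 0) 1 - sum((cumrel - pred)^2) / tss else NA_real_
  if (!is.na(r2) && r2 < 0.5) {
    warning("quality warning: first-order model explains little of the data (R2 = ",
            round(r2, 3), ")")
  }
  release_model(min(est[["minf"]], 100), est[["k"]], r2 = r2)
}
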