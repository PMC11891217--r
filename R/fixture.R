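#' The 29-run extraction experiment
#'
#' The packaged dataset of the microwave-assisted extraction study: a
#' four-factor, three-level Box-Behnken design with 29 runs (24 edge runs
#' plus 5 center replicates) and the measured polysaccharide yield (%) for
#' each run. Settings are stored in actual units; yields are percentages
#' (4.170 means 4.170%).
#'
#' Note on provenance: the published run sheet mislabels its factor columns.
#' The level sets identify them unambiguously -- 60/80/100 is the extraction
#' temperature (degC), 60/90/120 the extraction time (min) and 300/400/500
#' the microwave power (W) -- and this mapping is the one consistent with
#' the reported optimum settings and with the published regression equation,
#' whose evaluation at the center point reproduces the published center
#' prediction.
#'
#' @return A [design_table()] with 29 runs and `yield_pct` as response.
#' @seealso [prac_fixture()] for the version bundled with the published
#'   per-model predictions.
#' @export
prac_design <- function() {
  path <- system.file("extdata", "prac_bbd29.csv", package = "pracopt",
                      mustWork = TRUE)
  d <- load_design(path, factors = prac_factors(), response_col = "yield_pct")
  stopifnot(nrow(d$runs) == 29L, sum(is_center_run(d)) == 5L)
  d
}

#' The 29-run experiment with the four published model predictions
#'
#' Bundles the measured yields with the per-run predictions published for
#' the four fitted models: the Box-Behnken (quadratic response-surface)
#' model and the BP, GA-BP and GA-ACO-BP neural networks.
#'
#' @return A list of class `"prac_fixture"` with elements `design` (a
#'   [design_table()]) and `predicted`, a named list of four numeric
#'   29-vectors (`"box-behnken"`, `"bp"`, `"ga-bp"`, `"ga-aco-bp"`).
#' @export
prac_fixture <- function() {
  design <- prac_design()
  path <- system.file("extdata", "prac_bbd29_predictions.csv",
                      package = "pracopt", mustWork = TRUE)
  p <- utils::read.csv(path)
  stopifnot(identical(p$run, design$runs$run))
  predicted <- list(
    "box-behnken" = p$pred_bbd,
    "bp"          = p$pred_bp,
    "ga-bp"       = p$pred_gabp,
    "ga-aco-bp"   = p$pred_gaacobp
  )
  y <- design$runs$response
  # transcription guards: published range of the measured yields
  stopifnot(abs(min(y) - 2.149) < 1e-9, abs(max(y) - 4.170) < 1e-9)
  structure(list(design = design, predicted = predicted),
            class = "prac_fixture")
}

#' @export
print.prac_fixture <- function(x, ...) {
  cat("29-run Box-Behnken extraction experiment with predictions from",
      length(x$predicted), "models:\n ",
      paste(names(x$predicted), collapse = ", "), "\n")
  invisible(x)
}

#' Published second-order regression equation for the extraction yield
#'
#' The quadratic polynomial reported for the fitted yield surface, with its
#' coefficients in actual units exactly as printed (rounded by the authors).
#' Because of that rounding it drifts from a fresh least-squares refit by
#' about 0.01 in predicted yield; use [fit_quadratic()] on [prac_design()]
#' when full-precision coefficients are wanted.
#'
#' @return A `"quadratic_model"` (see [quadratic_model()]) in actual units.
#' @export
prac_printed_model <- function() {
  quadratic_model(
    intercept = -0.2634,
    linear = c(0.249903, -0.042711, -0.024221, 0.007521),
    interaction = c(0.001432, -0.000333, -0.00022,   # AB, AC, AD
                    0.000246, -0.000029, -0.000043), # BC, BD, CD
    quadratic = c(-0.004767, 0.00023, 0.000179, 4.76e-6),
    units = "actual", factors = prac_factors()
  )
}
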