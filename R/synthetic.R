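#' Generate a Box-Behnken design
#'
#' Standard three-level construction for k factors: for every pair of
#' factors, the four runs with that pair at its low/high levels and all
#' other factors at center (4 * choose(k, 2) edge runs), followed by
#' `n_center` center replicates. Run order is deterministic
#' (pair-lexicographic, then centers) so simulated experiments are exactly
#' reproducible; the randomized run order a DoE program would print is not
#' emulated.
#'
#' @param factors Factor data frame (see [factor_spec()]), 3 to 7 rows.
#' @param n_center Number of center replicates.
#' @return A [design_table()] without responses. For k = 4 and 5 center
#'   points this is the 29-run layout of the extraction study.
#' @export
generate_bbd <- function(factors, n_center = 5) {
  k <- nrow(factors)
  if (k < 3 || k > 7) stop("Box-Behnken construction supported for 3-7 factors")
  stopifnot(n_center >= 0)
  pairs <- utils::combn(k, 2)
  signs <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  coded <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(t) {
    m <- matrix(0, 4, k)
    m[, pairs[1, t]] <- signs[, 1]
    m[, pairs[2, t]] <- signs[, 2]
    m
  }))
  coded <- rbind(coded, matrix(0, n_center, k))
  design_table(factors, decode_settings(coded, factors))
}

#' Specify a true response surface for simulation
#'
#' The data-generating assumption behind a Box-Behnken experiment: a true
#' quadratic trend plus i.i.d. Gaussian replicate noise, optionally with a
#' smooth non-quadratic perturbation (a product-cosine bump in coded units
#' on one factor pair) to emulate model inadequacy / lack of fit.
#'
#' @param true_model A `"quadratic_model"` giving the noise-free surface.
#' @param noise_sd Response standard deviation (>= 0), same units as the
#'   response.
#' @param perturbation Optional list with `amplitude` and `factors`
#'   (indices of the factor pair); adds
#'   `amplitude * cos(pi c_i) * cos(pi c_j)` in coded units, which is
#'   non-zero at the design's own levels and invisible to the quadratic
#'   basis.
#' @return A list of class `"surface_spec"`.
#' @export
surface_spec <- function(true_model, noise_sd, perturbation = NULL) {
  stopifnot(inherits(true_model, "quadratic_model"), noise_sd >= 0)
  if (!is.null(perturbation)) {
    stopifnot(is.numeric(perturbation$amplitude),
              length(perturbation$factors) == 2)
  }
  structure(list(true_model = true_model, noise_sd = noise_sd,
                 perturbation = perturbation), class = "surface_spec")
}

#' Simulate responses for a design
#'
#' Evaluates the true surface at each run and adds seeded i.i.d. Gaussian
#' noise.
#'
#' @param design A [design_table()] (responses, if any, are replaced).
#' @param spec A [surface_spec()].
#' @param seed Integer seed.
#' @return The design with simulated responses filled in.
#' @export
simulate_response <- function(design, spec, seed) {
  s <- design_settings(design)
  model <- convert_units(spec$true_model, "actual")
  mu <- predict(model, s)
  if (!is.null(spec$perturbation)) {
    cc <- code_settings(s, design$factors)
    ij <- spec$perturbation$factors
    mu <- mu + spec$perturbation$amplitude *
      cos(pi * cc[, ij[1]]) * cos(pi * cc[, ij[2]])
  }
  eps <- withr::with_seed(seed, stats::rnorm(length(mu), 0, spec$noise_sd))
  design_table(design$factors, s, response = mu + eps,
               run = design$runs$run)
}

#' Surface specification mimicking the extraction study
#'
#' The published regression polynomial as the true surface, with Gaussian
#' noise at the scale of the fitted model's residual mean square
#' (sqrt(0.058), about 0.24% yield).
#'
#' @return A [surface_spec()].
#' @export
paper_like_spec <- function() {
  surface_spec(prac_printed_model(), noise_sd = sqrt(0.058))
}
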