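#' Define an experimental factor for a three-level design
#'
#' A factor in a Box-Behnken design is run at three equally spaced levels:
#' low, center and high, in actual (physical) units. The center must be the
#' midpoint of low and high, which is what makes the usual -1/0/+1 coding
#' exact.
#'
#' @param name Factor name (used as a column name in design tables).
#' @param unit Physical unit, e.g. `"mL/g"` or `"W"`; informational.
#' @param low,high Low and high levels in actual units, `low < high`.
#' @param center Center level; defaults to `(low + high) / 2` and must equal
#'   it to within `1e-9` of the half-range.
#' @return A one-row data frame with columns `name`, `unit`, `low`, `center`,
#'   `high`.
#' @examples
#' factor_spec("temperature_C", "degC", 60, 100)
#' @export
factor_spec <- function(name, unit, low, high, center = (low + high) / 2) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), is.numeric(high), is.numeric(center))
  if (!(low < center && center < high)) {
    stop("factor '", name, "': levels must satisfy low < center < high")
  }
  if (abs(center - (low + high) / 2) > 1e-9 * max(1, (high - low) / 2)) {
    stop("factor '", name, "': center must be the midpoint of low and high")
  }
  data.frame(name = name, unit = unit, low = low, center = center,
             high = high, stringsAsFactors = FALSE)
}

#' The four extraction-process factors
#'
#' Factor ranges used throughout the microwave-assisted extraction study:
#' liquid-to-solid ratio (14-22 mL/g), extraction temperature (60-100 degC),
#' extraction time (60-120 min) and microwave power (300-500 W).
#'
#' @return A four-row factor data frame (see [factor_spec()]).
#' @export
prac_factors <- function() {
  rbind(
    factor_spec("ratio_mL_per_g", "mL/g", 14, 22),
    factor_spec("temperature_C",  "degC", 60, 100),
    factor_spec("time_min",       "min",  60, 120),
    factor_spec("power_W",        "W",    300, 500)
  )
}

#' Construct a design table
#'
#' Couples a set of three-level factors with a run sheet: one row per
#' experimental run, holding the factor settings in actual units and an
#' optional measured response.
#'
#' @param factors Factor data frame, rows created by [factor_spec()].
#' @param settings Numeric matrix or data frame, one column per factor, in
#'   the order of `factors`.
#' @param response Optional numeric vector of measured responses (use `NA`
#'   for unmeasured runs, or omit entirely).
#' @param run Optional integer run identifiers; defaults to `1:n`.
#' @param check_levels If `TRUE` (default), require every setting to be one
#'   of that factor's three declared levels, as in a Box-Behnken table.
#' @return An object of class `"design_table"`: a list with elements
#'   `factors` and `runs` (a data frame `run`, one column per factor,
#'   `response`).
#' @export
design_table <- function(factors, settings, response = NULL, run = NULL,
                         check_levels = TRUE) {
  settings <- as.matrix(settings)
  k <- nrow(factors)
  if (ncol(settings) != k) {
    stop("settings has ", ncol(settings), " columns but there are ", k,
         " factors")
  }
  n <- nrow(settings)
  if (is.null(run)) run <- seq_len(n)
  if (is.null(response)) response <- rep(NA_real_, n)
  stopifnot(length(run) == n, length(response) == n)
  colnames(settings) <- factors$name
  if (check_levels) {
    for (j in seq_len(k)) {
      lev <- c(factors$low[j], factors$center[j], factors$high[j])
      bad <- which(!vapply(settings[, j],
                           function(v) any(abs(v - lev) <= 1e-9 * max(1, abs(lev))),
                           logical(1)))
      if (length(bad)) {
        stop("factor '", factors$name[j], "': setting ", settings[bad[1], j],
             " in run ", run[bad[1]], " is not one of its three levels (",
             paste(lev, collapse = ", "), ")")
      }
    }
  }
  runs <- data.frame(run = as.integer(run), settings, response = response,
                     check.names = FALSE)
  structure(list(factors = factors, runs = runs), class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  cat("Design table: ", nrow(x$runs), " runs, ", nrow(x$factors),
      " factors (", paste(x$factors$name, collapse = ", "), ")\n", sep = "")
  cat(sum(is_center_run(x)), "center replicate(s);",
      sum(!is.na(x$runs$response)), "measured response(s)\n")
  print(utils::head(x$runs, 6), ...)
  if (nrow(x$runs) > 6) cat("...\n")
  invisible(x)
}

#' Settings matrix of a design table
#' @param design A `design_table`.
#' @return Numeric matrix, runs by factors, in actual units.
#' @export
design_settings <- function(design) {
  as.matrix(design$runs[, design$factors$name, drop = FALSE])
}

#' Identify center replicates
#'
#' @param design A `design_table`.
#' @return Logical vector: `TRUE` for runs with every factor at its center
#'   level.
#' @export
is_center_run <- function(design) {
  s <- design_settings(design)
  ctr <- design$factors$center
  apply(s, 1, function(r) all(abs(r - ctr) <= 1e-9 * pmax(1, abs(ctr))))
}

#' Read a design table from CSV
#'
#' The file must have a header row with a `run` column, one numeric column
#' per factor and, optionally, one response column. When `factors` is not
#' supplied, factor columns are recognised as those whose values fall on
#' exactly three levels with the middle level at the midpoint; any single
#' remaining numeric column is taken as the response.
#'
#' @param path Path to a comma-separated file ('.' decimal, UTF-8).
#' @param factors Optional factor data frame; when given, factor columns are
#'   matched by name and levels are validated against it.
#' @param response_col Optional response column name; overrides detection.
#' @return A [design_table()].
#' @export
load_design <- function(path, factors = NULL, response_col = NULL) {
  raw <- tryCatch(utils::read.csv(path, check.names = FALSE),
                  error = function(e) stop("schema error: cannot read '",
                                           path, "': ", conditionMessage(e)))
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("schema error: '", path, "' has no data rows")
  }
  if (!"run" %in% names(raw)) {
    stop("schema error: missing 'run' column in '", path, "'")
  }
  for (nm in setdiff(names(raw), "run")) {
    vals <- raw[[nm]]
    if (!is.numeric(vals)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(vals)))))[1]
      stop("parse error: non-numeric value in column '", nm, "', row ",
           if (is.na(bad)) "?" else bad)
    }
  }
  cols <- setdiff(names(raw), "run")
  if (is.null(factors)) {
    looks_like_levels <- function(v) {
      u <- sort(unique(v))
      length(u) == 3L && abs(u[2] - (u[1] + u[3]) / 2) <= 1e-9 * max(1, abs(u[3]))
    }
    fac_cols <- cols[vapply(raw[cols], looks_like_levels, logical(1))]
    rest <- setdiff(cols, fac_cols)
    if (!is.null(response_col)) {
      fac_cols <- setdiff(cols, response_col)
      rest <- response_col
    }
    if (length(rest) > 1L) {
      stop("schema error: cannot identify the response among columns ",
           paste(rest, collapse = ", "), "; pass response_col")
    }
    factors <- do.call(rbind, lapply(fac_cols, function(nm) {
      u <- sort(unique(raw[[nm]]))
      factor_spec(nm, unit = "", low = u[1], high = u[3], center = u[2])
    }))
    response <- if (length(rest) == 1L) raw[[rest]] else NULL
  } else {
    miss <- setdiff(factors$name, cols)
    if (length(miss)) {
      stop("schema error: missing factor column(s) ",
           paste(miss, collapse = ", "))
    }
    if (is.null(response_col)) {
      rest <- setdiff(cols, factors$name)
      if (length(rest) > 1L) stop("schema error: ambiguous response column")
      response_col <- if (length(rest)) rest else NULL
    }
    response <- if (is.null(response_col)) NULL else raw[[response_col]]
  }
  design_table(factors, raw[, factors$name, drop = FALSE],
               response = response, run = raw$run)
}

#' Convert design settings between actual and coded units
#'
#' Standard Box-Behnken coding: low maps to -1, center to 0, high to +1.
#' `to_coded()` requires every setting to sit on a declared level;
#' `code_settings()`/`decode_settings()` apply the affine transform to
#' arbitrary matrices (used by the response-surface machinery).
#'
#' @param design A `design_table` in actual units.
#' @return For `to_coded()`, a numeric matrix of -1/0/+1 values with one
#'   column per factor.
#' @export
to_coded <- function(design) {
  s <- design_settings(design)
  coded <- code_settings(s, design$factors)
  off <- abs(coded - round(coded)) > 1e-9
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)[1, ]
    stop("coding error: run ", design$runs$run[ij[1]], ", factor '",
         design$factors$name[ij[2]], "' value ", s[ij[1], ij[2]],
         " is not at a declared level")
  }
  round(coded)
}

#' @rdname to_coded
#' @param settings Numeric matrix (or vector for a single run), columns in
#'   factor order.
#' @param factors Factor data frame.
#' @export
code_settings <- function(settings, factors) {
  settings <- if (is.null(dim(settings))) matrix(settings, nrow = 1) else as.matrix(settings)
  half <- (factors$high - factors$low) / 2
  out <- sweep(sweep(settings, 2, factors$center, "-"), 2, half, "/")
  colnames(out) <- factors$name
  out
}

#' @rdname to_coded
#' @param coded Numeric matrix of coded settings.
#' @export
decode_settings <- function(coded, factors) {
  coded <- if (is.null(dim(coded))) matrix(coded, nrow = 1) else as.matrix(coded)
  half <- (factors$high - factors$low) / 2
  out <- sweep(sweep(coded, 2, half, "*"), 2, factors$center, "+")
  colnames(out) <- factors$name
  out
}
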