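#' Raw (possibly irregular) cell-index series
#'
#' Container for a single curve before interpolation onto the common grid:
#' observation times in hours (strictly increasing, at least 4 points so a
#' cubic spline is defined) and cell-index values, plus the usual per-curve
#' annotations.
#'
#' @param times Strictly increasing numeric vector (hours).
#' @param values Numeric vector, same length.
#' @param info One-row data frame of annotations (see [curve_panel()]).
#' @return An object of class `raw_series`.
#' @export
raw_series <- function(times, values, info = NULL) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop_tcrc("tcrcfda_shape_error", "times and values differ in length")
  }
  if (length(times) < 4L) {
    stop_tcrc("tcrcfda_invalid_series", "a raw series needs >= 4 points")
  }
  if (any(diff(times) <= 0)) {
    stop_tcrc("tcrcfda_invalid_series", "times must be strictly increasing")
  }
  structure(list(times = times, values = values, info = info),
            class = "raw_series")
}

#' Cell index from frequency-dependent impedance
#'
#' The impedance reader records electrode impedance at several frequencies
#' with and without cells; the Cell Index is the largest relative impedance
#' increase over frequencies: `CI = max_i(R_cell(f_i) / R_b(f_i) - 1)`.
#'
#' @param r_cell Impedance with cells, one value per frequency.
#' @param r_b Background impedance (no cells), same length, strictly positive.
#' @return The scalar cell index.
#' @export
#' @examples
#' cell_index_from_impedance(c(1.5, 3, 2), c(1, 1, 1)) # 2
cell_index_from_impedance <- function(r_cell, r_b) {
  if (length(r_cell) != length(r_b) || length(r_b) < 1L) {
    stop_tcrc("tcrcfda_shape_error", "r_cell and r_b must have equal length >= 1")
  }
  if (any(r_b <= 0)) {
    stop_tcrc("tcrcfda_domain_error", "background impedance must be strictly positive")
  }
  max(r_cell / r_b - 1)
}

#' Normalize a cell-index series to the Normalized Cell Index scale
#'
#' `NCI[k] = CI[k] / CI[0]`, where `k = 0` is the time point right before
#' treatment. Anchoring every curve at one removes well-to-well differences in
#' cell density at treatment time. If `t0_value` is omitted, the first point
#' of the series is taken as the pre-treatment anchor `CI[0]` and dropped from
#' the output (the stored series then starts at `k = 1`); otherwise all
#' points are retained and divided by `t0_value`.
#'
#' @param series A [raw_series()] on the CI scale.
#' @param t0_value Optional CI value at treatment time; must be positive.
#' @return A [raw_series()] on the NCI scale.
#' @export
normalize_nci <- function(series, t0_value = NULL) {
  stopifnot(inherits(series, "raw_series"))
  if (is.null(t0_value)) {
    t0_value <- series$values[1]
    if (t0_value <= 0) stop_tcrc("tcrcfda_domain_error", "CI[0] must be positive")
    raw_series(series$times[-1], series$values[-1] / t0_value, series$info)
  } else {
    if (t0_value <= 0) stop_tcrc("tcrcfda_domain_error", "t0_value must be positive")
    raw_series(series$times, series$values / t0_value, series$info)
  }
}

#' Interpolate a raw series onto a uniform time grid
#'
#' Cubic-spline evaluation at the target grid. With `penalty = 0` the curve
#' interpolates the observations exactly (and reproduces polynomials of
#' degree up to three); with a positive penalty, or `penalty = "auto"`
#' (generalized cross-validation), a cubic smoothing spline is used.
#' Extrapolation is never performed: a grid extending beyond the observed
#' time range is an error, because fabricated late-time behaviour would feed
#' directly into the downstream models.
#'
#' @param series A [raw_series()].
#' @param grid Target time grid, within the observed range.
#' @param penalty `0` (default) for exact interpolation, a positive smoothing
#'   parameter (`lambda` of [stats::smooth.spline()]), or `"auto"` for GCV.
#' @return Numeric vector of values on `grid`.
#' @export
to_uniform_grid <- function(series, grid, penalty = 0) {
  stopifnot(inherits(series, "raw_series"))
  grid <- as.numeric(grid)
  if (min(grid) < min(series$times) - 1e-9 || max(grid) > max(series$times) + 1e-9) {
    stop_tcrc("tcrcfda_extrapolation_error",
              "grid [%g, %g] extends beyond observed range [%g, %g]",
              min(grid), max(grid), min(series$times), max(series$times))
  }
  if (identical(penalty, "auto")) {
    fit <- stats::smooth.spline(series$times, series$values, cv = FALSE)
    stats::predict(fit, grid)$y
  } else if (is.numeric(penalty) && penalty > 0) {
    fit <- stats::smooth.spline(series$times, series$values, lambda = penalty)
    stats::predict(fit, grid)$y
  } else {
    stats::spline(series$times, series$values, xout = grid, method = "fmm")$y
  }
}

#' Interpolate all pending curves of a panel onto its grid
#'
#' Applies [to_uniform_grid()] to every raw series flagged by
#' [read_curve_panel()] as having missing time points, and merges the result
#' into the panel.
#'
#' @param panel A [curve_panel()] possibly carrying a
#'   `pending_interpolation` attribute.
#' @param penalty Passed to [to_uniform_grid()].
#' @return A [curve_panel()] with all curves on the grid.
#' @export
resolve_pending <- function(panel, penalty = 0) {
  pending <- attr(panel, "pending_interpolation")
  if (is.null(pending) || !length(pending)) return(panel)
  extra <- t(vapply(pending, function(s) to_uniform_grid(s, panel$grid, penalty),
                    numeric(length(panel$grid))))
  info <- rbind(panel$info, do.call(rbind, lapply(pending, `[[`, "info")))
  curve_panel(panel$grid, rbind(panel$curves, extra), info, scale = panel$scale)
}
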