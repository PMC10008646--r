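# Orthonormal Daubechies scaling (lowpass) filters, ascending index.
# Standard published coefficient values; "dbN" has N vanishing moments and
# filter length 2N. The quadrature-mirror highpass is derived from these.
daubechies_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079,
          0.2241438680420134, -0.12940952255126037),
  db3 = c(0.33267055295008263, 0.8068915093110925, 0.45987750211849154,
          -0.13501102001025458, -0.08544127388202666, 0.03522629188570953),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032)
)

get_wavelet_filter <- function(wavelet) {
  h <- daubechies_filters[[wavelet]]
  if (is.null(h)) {
    stop_tcrc("tcrcfda_config_error", "unknown wavelet family '%s' (available: %s)",
              wavelet, paste(names(daubechies_filters), collapse = ", "))
  }
  h
}

# One periodized decomposition step. Odd-length signals are first extended by
# repeating the last sample (so the constant-signal identity is preserved),
# then treated as circular; output length is ceil(n / 2).
dwt_step <- function(x, h) {
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  n <- length(x)
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror highpass
  half <- n %/% 2L
  idx <- outer(2 * seq_len(half) - 2, seq_along(h) - 1, "+") %% n + 1L
  xm <- matrix(x[idx], half, length(h))
  list(approx = as.numeric(xm %*% h), detail = as.numeric(xm %*% g))
}

#' Multi-level periodized discrete wavelet transform
#'
#' Cascaded orthonormal DWT with circular (periodized) signal extension,
#' returning the approximation (scaling) coefficients at the final level and
#' the detail coefficients of every level. For even lengths each step is an
#' orthogonal transform (energy preserving); odd intermediate lengths are
#' handled by repeating the last sample before periodizing, as is standard
#' for non-dyadic signal lengths.
#'
#' @param x Numeric signal.
#' @param level Number of cascaded decompositions (>= 1).
#' @param wavelet Filter family name (`"haar"`, `"db1"`.. `"db4"`).
#' @return List with `approx` (final-level scaling coefficients) and
#'   `details` (list of per-level detail coefficients).
#' @export
dwt_periodized <- function(x, level, wavelet = "db4") {
  h <- get_wavelet_filter(wavelet)
  if (!is.numeric(level) || length(level) != 1L || level < 1 || level != round(level)) {
    stop_tcrc("tcrcfda_config_error", "decomposition level must be an integer >= 1")
  }
  if (length(x) < length(h)) {
    stop_tcrc("tcrcfda_config_error",
              "signal length %d shorter than filter length %d", length(x), length(h))
  }
  details <- vector("list", level)
  a <- as.numeric(x)
  for (l in seq_len(level)) {
    st <- dwt_step(a, h)
    a <- st$approx
    details[[l]] <- st$detail
  }
  list(approx = a, details = details)
}

#' Scaling (approximation) coefficients of a curve
#'
#' The lowpass output after `level` cascaded wavelet decompositions: a short,
#' smooth summary of the curve used as the feature vector for functional
#' k-means clustering of TCRCs. A 72-point hourly curve at level 4 yields 5
#' coefficients; 11 concatenated curves (792 points) yield 50.
#'
#' @inheritParams dwt_periodized
#' @return Numeric vector of scaling coefficients.
#' @export
#' @examples
#' length(dwt_scaling_coeffs(sin(1:72 / 8), level = 4)) # 5
dwt_scaling_coeffs <- function(x, level, wavelet = "db4") {
  dwt_periodized(x, level, wavelet)$approx
}
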