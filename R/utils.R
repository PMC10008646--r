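#' Trapezoid quadrature weights
#'
#' Weights \code{w} such that \code{sum(w * f)} approximates the integral of
#' \code{f} over the range of \code{grid} by the trapezoid rule. Used
#' throughout for functional inner products on the common hourly grid.
#'
#' @param grid Strictly increasing numeric vector of evaluation points.
#' @return Numeric vector of weights, same length as \code{grid}.
#' @keywords internal
trapezoid_weights <- function(grid) {
  stopifnot(is.numeric(grid), length(grid) >= 2L, all(diff(grid) > 0))
  h <- diff(grid)
  w <- numeric(length(grid))
  w[1] <- h[1] / 2
  w[length(grid)] <- h[length(h)] / 2
  if (length(grid) > 2L) {
    w[2:(length(grid) - 1L)] <- (h[-length(h)] + h[-1]) / 2
  }
  w
}

#' Derive a stage-specific random seed from the master seed
#'
#' Every stochastic pipeline stage receives its own seed, derived
#' deterministically from the master seed and the stage name, so that partial
#' re-runs of a stage reproduce the full-pipeline result.
#'
#' @param master Integer master seed.
#' @param stage Character stage name (e.g. \code{"binning"}).
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
#' @examples
#' derive_seed(1L, "binning")
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master), master == round(master),
            is.character(stage), length(stage) == 1L)
  # polynomial rolling hash of the stage name, mod a Mersenne prime < 2^31
  p <- 2147483647
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% p
  as.integer((abs(master) %% p * 7919 + h) %% p)
}

#' Internal: stop with a classed condition
#' @noRd
stop_tcrc <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "tcrcfda_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
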