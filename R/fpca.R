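#' Level-specific mean functions
#'
#' Estimates the fixed concentration effect \eqn{\mu_\tau(t)} of the
#' functional mixed model as the pointwise average of all curves at binned
#' level \eqn{\tau}, optionally followed by light spline smoothing.
#'
#' @param panel A binned [curve_panel()].
#' @param penalty Smoothing penalty applied to each mean curve: `0` (default)
#'   for the raw pointwise average, a positive `lambda`, or `"auto"` for GCV.
#' @return An object of class `mean_model`: list of mean curves per level.
#' @export
estimate_means <- function(panel, penalty = 0) {
  stopifnot(inherits(panel, "curve_panel"))
  lev <- panel$info$binned_level
  if (any(is.na(lev))) {
    stop_tcrc("tcrcfda_contract_error", "panel must be binned before estimating means")
  }
  mu <- lapply(stats::setNames(unique(lev), unique(lev)), function(l) {
    rows <- which(lev == l)
    if (!length(rows)) stop_tcrc("tcrcfda_coverage_error", "no curves at level %s", l)
    m <- colMeans(panel$curves[rows, , drop = FALSE])
    if (!identical(penalty, 0)) {
      m <- to_uniform_grid(raw_series(panel$grid, m), panel$grid, penalty)
    }
    m
  })
  structure(list(mu = mu, grid = panel$grid), class = "mean_model")
}

panel_residuals <- function(panel, means) {
  lev <- panel$info$binned_level
  res <- panel$curves
  for (l in unique(lev)) {
    rows <- lev == l
    res[rows, ] <- sweep(panel$curves[rows, , drop = FALSE], 2, means$mu[[l]])
  }
  res
}

#' Moment-based covariance separation of chemical and smooth-error processes
#'
#' Separates, from residual curves \eqn{r = Y - \hat\mu_\tau}, the
#' covariance surface of the concentration-specific chemical random
#' intercept \eqn{K_{B,\tau}(s,t)} from that of the curve-specific smooth
#' error \eqn{K_E(s,t)} and the white-noise variance \eqn{\sigma^2}:
#' \itemize{
#' \item \eqn{\hat K_{B,\tau}} averages cross-products
#'   \eqn{r_o(s) r_{o'}(t)} over ordered replicate pairs \eqn{o \neq o'}
#'   within each (level, chemical) cell — replicates share the chemical
#'   effect but have independent smooth errors, so cross-products isolate
#'   \eqn{K_B}; the result is symmetrized.
#' \item \eqn{\hat K_E} is the average over curves of
#'   \eqn{r r^T - \hat K_{B,\tau(curve)}}, whose off-diagonal estimates
#'   \eqn{K_E}; its diagonal (contaminated by \eqn{\sigma^2}) is replaced by
#'   linear extrapolation along the ridge from the first two off-diagonals.
#' \item \eqn{\hat\sigma^2} is the average remaining diagonal deficit,
#'   truncated at zero.
#' }
#' Control curves carry no chemical effect: they contribute to \eqn{K_E} and
#' \eqn{\sigma^2} only.
#'
#' @param panel A binned [curve_panel()].
#' @param means A [estimate_means()] fit.
#' @return An object of class `cov_model` with `K_B` (list of surfaces per
#'   level), `K_E`, and `sigma2`.
#' @export
estimate_covariances <- function(panel, means) {
  stopifnot(inherits(panel, "curve_panel"), inherits(means, "mean_model"))
  res <- panel_residuals(panel, means)
  lev <- panel$info$binned_level
  T_ <- ncol(res)
  chem_levels <- setdiff(unique(lev), "none")
  K_B <- stats::setNames(vector("list", length(chem_levels)), chem_levels)
  any_pairs <- FALSE
  for (l in chem_levels) {
    rows <- which(lev == l)
    R <- res[rows, , drop = FALSE]
    chem <- panel$info$chemical_id[rows]
    ind <- outer(chem, unique(chem), "==") + 0  # curves x chemicals
    n_o <- colSums(ind)
    n_pairs <- sum(n_o * (n_o - 1))
    if (n_pairs == 0) {
      K_B[[l]] <- matrix(0, T_, T_)
      next
    }
    any_pairs <- TRUE
    S <- crossprod(ind, R)                    # per-chemical residual sums
    K <- (crossprod(S) - crossprod(R)) / n_pairs
    K_B[[l]] <- (K + t(K)) / 2
  }
  if (!any_pairs) {
    stop_tcrc("tcrcfda_identifiability_error",
              "no replicated (level, chemical) cells: chemical and smooth-error processes are inseparable")
  }
  # pooled within-curve second moment minus the curve's chemical block
  M <- crossprod(res) / nrow(res)
  KB_mean <- matrix(0, T_, T_)
  for (l in unique(lev)) {
    w_l <- mean(lev == l)
    if (l %in% chem_levels) KB_mean <- KB_mean + w_l * K_B[[l]]
  }
  K_E <- M - KB_mean
  # diagonal carries sigma^2; refill by linear extrapolation along the ridge
  raw_diag_deficit <- diag(K_E)
  off_mean <- function(t, d) {
    js <- c(t - d, t + d)
    js <- js[js >= 1 & js <= T_]
    mean(K_E[t, js])
  }
  dg <- vapply(seq_len(T_), function(t) 2 * off_mean(t, 1L) - off_mean(t, 2L),
               numeric(1))
  sigma2 <- max(0, mean(raw_diag_deficit - dg))
  diag(K_E) <- dg
  K_E <- (K_E + t(K_E)) / 2
  structure(list(K_B = K_B, K_E = K_E, sigma2 = sigma2, grid = panel$grid),
            class = "cov_model")
}

#' Quadrature-weighted eigendecomposition of a covariance surface
#'
#' Solves the functional eigenproblem of the covariance operator on the
#' grid: with trapezoid weights \eqn{W}, the symmetric matrix
#' \eqn{W^{1/2} K W^{1/2}} is eigendecomposed, negative eigenvalues are
#' dropped (positive-semidefinite projection), and eigenfunctions
#' \eqn{\phi = W^{-1/2} v} are returned quadrature-orthonormal. The sign
#' gauge: \eqn{\int \phi \ge 0}; if that integral is negligible, the first
#' non-negligible grid value is made positive.
#'
#' @param K Symmetric covariance surface (T x T).
#' @param grid Time grid.
#' @param n_keep Number of components to retain, or `NULL` to retain enough
#'   for `var_threshold`.
#' @param var_threshold Fraction of (positive-part) variance to retain when
#'   `n_keep` is `NULL`.
#' @return List with `values` (nonincreasing eigenvalues), `functions`
#'   (T x K matrix), and `varprop` (variance-explained proportions relative
#'   to the full positive spectrum).
#' @export
eigendecompose <- function(K, grid, n_keep = NULL, var_threshold = 0.95) {
  if (max(abs(K - t(K))) > 1e-10) {
    stop_tcrc("tcrcfda_contract_error", "covariance surface is not symmetric")
  }
  w <- trapezoid_weights(grid)
  sw <- sqrt(w)
  A <- K * tcrossprod(sw)
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-12 & eg$values > 0
  values <- eg$values[pos]
  vectors <- eg$vectors[, pos, drop = FALSE]
  total <- sum(values)
  if (!length(values)) {
    return(list(values = numeric(0), functions = matrix(0, length(grid), 0),
                varprop = numeric(0)))
  }
  keep <- if (!is.null(n_keep)) min(n_keep, length(values)) else {
    which(cumsum(values) / total >= var_threshold)[1]
  }
  values <- values[seq_len(keep)]
  phi <- vectors[, seq_len(keep), drop = FALSE] / sw
  for (k in seq_len(keep)) {
    s <- sum(w * phi[, k])
    if (abs(s) >= 1e-8) {
      if (s < 0) phi[, k] <- -phi[, k]
    } else {
      lead <- which(abs(phi[, k]) > 1e-8 * max(abs(phi[, k])))[1]
      if (phi[lead, k] < 0) phi[, k] <- -phi[, k]
    }
  }
  list(values = values, functions = phi, varprop = values / total)
}

#' Fit the fPCA functional mixed model to a binned panel
#'
#' Convenience wrapper running [estimate_means()], [estimate_covariances()]
#' and [eigendecompose()] for every chemical-effect block (one per binned
#' level, 3 components each by default — the first three functional
#' principal components carry almost all chemical-induced variability) and
#' for the smooth-error block (variance-threshold truncation).
#'
#' @param panel A binned [curve_panel()].
#' @param n_fpc Components per chemical-effect block.
#' @param e_var_threshold Variance threshold for the smooth-error block.
#' @param mean_penalty Passed to [estimate_means()].
#' @return An object of class `fpc_model` with elements `means`, `cov`,
#'   `blocks` (eigenpairs per level), `E` (smooth-error eigenpairs), and
#'   `sigma2`.
#' @export
fit_fpca <- function(panel, n_fpc = 3L, e_var_threshold = 0.95, mean_penalty = 0) {
  means <- estimate_means(panel, penalty = mean_penalty)
  cv <- estimate_covariances(panel, means)
  blocks <- lapply(cv$K_B, eigendecompose, grid = panel$grid, n_keep = n_fpc)
  E <- eigendecompose(cv$K_E, panel$grid, n_keep = NULL,
                      var_threshold = e_var_threshold)
  structure(list(means = means, cov = cv, blocks = blocks, E = E,
                 sigma2 = cv$sigma2, grid = panel$grid, n_fpc = n_fpc),
            class = "fpc_model")
}

#' @export
print.fpc_model <- function(x, ...) {
  cat("fpc_model:\n")
  for (l in names(x$blocks)) {
    cat(sprintf("  %-7s lambda = %s\n", l,
                paste(signif(x$blocks[[l]]$values, 4), collapse = ", ")))
  }
  cat(sprintf("  E block: %d component(s) | sigma2 = %.4g\n",
              length(x$E$values), x$sigma2))
  invisible(x)
}

#' BLUP prediction of chemical scores (V1..V9)
#'
#' Predicts, for each chemical and binned level, the Karhunen-Loeve scores
#' of the chemical random intercept under the working Gaussian model
#' (independent scores with variances \eqn{\lambda}, smooth error plus white
#' noise \eqn{\sigma^2 I} within curves). Replicate curves within a (level,
#' chemical) cell share the chemical effect, so the posterior mean depends
#' on the cell's average residual curve \eqn{\bar r}:
#' \deqn{\hat b = \Lambda \Phi^T \big(\Phi \Lambda \Phi^T +
#'   (\Phi_E \Lambda_E \Phi_E^T + \sigma^2 I)/n_o\big)^{-1} \bar r.}
#' Scores are laid out per chemical as V1..V3 (high), V4..V6 (medium),
#' V7..V9 (low) when three components per level are retained. Chemicals with
#' no curves at some level get `NA` scores (flagged, never imputed).
#'
#' @param panel A binned [curve_panel()].
#' @param fit A [fit_fpca()] model.
#' @return Data frame (`score_table`): `chemical_id`, `moa_label`, V-columns.
#' @export
predict_scores <- function(panel, fit) {
  stopifnot(inherits(panel, "curve_panel"), inherits(fit, "fpc_model"))
  res <- panel_residuals(panel, fit$means)
  lev <- panel$info$binned_level
  level_order <- intersect(c("high", "medium", "low"), names(fit$blocks))
  level_order <- c(level_order, setdiff(names(fit$blocks), level_order))
  treated <- lev != "none"
  chems <- unique(panel$info$chemical_id[treated])
  Sigma_w <- fit$E$functions %*% (fit$E$values * t(fit$E$functions)) +
    diag(fit$sigma2, length(fit$grid))
  out <- list()
  for (l in level_order) {
    blk <- fit$blocks[[l]]
    K <- length(blk$values)
    Phi <- blk$functions
    KB <- Phi %*% (blk$values * t(Phi))
    sc <- matrix(NA_real_, length(chems), K)
    rows_l <- which(lev == l)
    for (ci in seq_along(chems)) {
      rows <- rows_l[panel$info$chemical_id[rows_l] == chems[ci]]
      if (!length(rows)) next  # missing level for this chemical: flagged NA
      rbar <- colMeans(res[rows, , drop = FALSE])
      A <- KB + Sigma_w / length(rows)
      sc[ci, ] <- as.numeric((blk$values * t(Phi)) %*% solve(A, rbar))
    }
    out[[l]] <- sc
  }
  scores <- do.call(cbind, out)
  colnames(scores) <- paste0("V", seq_len(ncol(scores)))
  moa <- panel$info$moa_label[match(chems, panel$info$chemical_id)]
  df <- data.frame(chemical_id = chems, moa_label = moa, scores,
                   stringsAsFactors = FALSE)
  attr(df, "level_order") <- level_order
  attr(df, "n_per_level") <- vapply(out, ncol, integer(1))
  class(df) <- c("score_table", "data.frame")
  df
}
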