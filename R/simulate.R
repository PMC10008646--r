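#' Simulation design for synthetic TCRC panels
#'
#' Describes the layout of a simulated experiment: how many chemicals per
#' mode-of-action (MOA) group, how many concentration levels per chemical
#' (a 1:3 serial dilution from the stock solution, index 1 = strongest),
#' how many untreated control curves, and how concentration indices map to
#' binned levels. The default reproduces the study layout: 63 chemicals
#' (20 in group 1, 13 in group 10, 30 in the combined remainder) at 11
#' concentrations plus 12 controls, i.e. 11 x 63 + 12 = 705 curves, observed
#' hourly over 72 h, with bins high = \{1..4\}, medium = \{5..8\},
#' low = \{9..11\}.
#'
#' @param groups Named integer vector: chemicals per MOA group.
#' @param concentrations Number of concentration indices per chemical.
#' @param n_controls Number of control curves.
#' @param bin_map Named list of integer vectors partitioning
#'   `1:concentrations` into binned levels.
#' @param grid Common time grid in hours.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(groups = c(group1 = 20L, group10 = 13L, other = 30L),
                              concentrations = 11L,
                              n_controls = 12L,
                              bin_map = list(high = 1:4, medium = 5:8, low = 9:11),
                              grid = 1:72) {
  stopifnot(all(groups > 0), concentrations >= 1, n_controls >= 0,
            length(names(groups)) == length(groups))
  idx <- sort(unlist(bin_map, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(concentrations))) {
    stop_tcrc("tcrcfda_invalid_design", "bin_map must partition 1..%d", concentrations)
  }
  structure(list(groups = groups, concentrations = as.integer(concentrations),
                 n_controls = as.integer(n_controls), bin_map = bin_map,
                 grid = as.numeric(grid)),
            class = "simulation_design")
}

# Smooth sigmoidal building block for mean shapes.
sigm <- function(t, center, slope) 1 / (1 + exp(-(t - center) / slope))

# Level-specific mean NCI curves emulating the four phases of the cell growth
# curve (lag, log, plateau, decline), anchored at 1 at the first grid point.
# High doses kill the cells (monotone decline towards 0); medium doses allow
# growth followed by chemically induced death; low doses and controls grow to
# a plateau with a mild natural decline.
default_mean_curves <- function(grid) {
  t1 <- grid[1]
  anchor <- function(f) {
    v <- f(grid) - f(t1) + 1
    v
  }
  list(
    high = anchor(function(t) 3 * (exp(-(t - t1) / 10) - 1) / 3 +
                    0.03 * sigm(t, 10, 4)),
    medium = anchor(function(t) 2.2 * sigm(t, 14, 5) - 2.6 * sigm(t, 40, 9)),
    low = anchor(function(t) 2.4 * sigm(t, 18, 6) - 0.5 * sigm(t, 60, 5)),
    none = anchor(function(t) 2.8 * sigm(t, 18, 6) - 0.4 * sigm(t, 60, 5))
  )
}

# Gram-Schmidt orthonormalization under trapezoid quadrature.
orthonormalize <- function(basis, w) {
  Q <- matrix(0, nrow(basis), ncol(basis))
  for (j in seq_len(ncol(basis))) {
    v <- basis[, j]
    if (j > 1L) {
      for (i in seq_len(j - 1L)) v <- v - sum(w * v * Q[, i]) * Q[, i]
    }
    nrm <- sqrt(sum(w * v * v))
    if (nrm < 1e-10) stop_tcrc("tcrcfda_capacity_error", "basis shapes are degenerate")
    Q[, j] <- v / nrm
  }
  Q
}

#' Build a generative truth model for synthetic TCRC panels
#'
#' Constructs the ingredients of the functional mixed-effects data-generating
#' process with known ground truth: level-specific mean functions
#' \eqn{\mu_\tau(t)} (rise-then-plateau for controls and low doses, decline
#' for high doses), quadrature-orthonormal eigenfunctions and eigenvalues for
#' the concentration-specific chemical random intercept (per binned level
#' \eqn{\tau}) and for the smooth error process, a white-noise variance, and
#' fixed per-group score offsets that separate the MOA groups in the first
#' two score dimensions by a configurable margin. All eigenfunctions vanish
#' at the first grid point, so simulated NCI curves start at 1 up to
#' measurement noise.
#'
#' @param design A [simulation_design()].
#' @param n_fpc Number of chemical-effect eigenfunctions per level (max 6).
#' @param seed Integer seed (kept for interface symmetry; construction is
#'   deterministic).
#' @param lambda_B Base chemical-effect eigenvalues, sorted nonincreasing.
#' @param tau_scale Named multipliers of `lambda_B` per binned level.
#' @param lambda_E Smooth-error eigenvalues.
#' @param sigma2 White-noise variance per grid point.
#' @param margin Group-separation margin: group score means are placed
#'   `margin * sqrt(lambda)` apart (per component, directions spread on the
#'   unit circle in the first two components). `margin = 0` makes groups
#'   indistinguishable in truth.
#' @return An object of class `truth_model`.
#' @export
make_truth <- function(design = simulation_design(), n_fpc = 3L, seed = 1L,
                       lambda_B = c(4, 1, 0.25), tau_scale = c(high = 1, medium = 0.6, low = 0.3),
                       lambda_E = c(0.5, 0.1), sigma2 = 0.01, margin = 1.5) {
  stopifnot(inherits(design, "simulation_design"), n_fpc >= 1)
  grid <- design$grid
  T_ <- length(grid)
  if (n_fpc > 6L) {
    stop_tcrc("tcrcfda_capacity_error", "at most 6 chemical-effect fPCs available, got %d", n_fpc)
  }
  if (length(lambda_B) < n_fpc) {
    stop_tcrc("tcrcfda_capacity_error", "lambda_B provides %d eigenvalues for n_fpc = %d",
              length(lambda_B), n_fpc)
  }
  lambda_B <- sort(lambda_B[seq_len(n_fpc)], decreasing = TRUE)
  lambda_E <- sort(lambda_E, decreasing = TRUE)
  stopifnot(all(lambda_B >= 0), all(lambda_E >= 0), sigma2 >= 0)
  w <- trapezoid_weights(grid)
  x <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  # Chemical-effect shapes: half-period sines (vanish at both ends); smooth
  # error: quarter-period sines (vanish at t1 only). Orthonormalized under
  # trapezoid quadrature.
  phi_B <- orthonormalize(sapply(seq_len(n_fpc), function(k) sin(k * pi * x)), w)
  phi_E <- orthonormalize(sapply(seq_along(lambda_E), function(k) sin((k - 0.5) * pi * x)), w)

  levels_used <- names(design$bin_map)
  if (!all(levels_used %in% c("high", "medium", "low"))) {
    stop_tcrc("tcrcfda_invalid_design", "bin_map names must be among high/medium/low")
  }
  bad <- setdiff(levels_used, names(tau_scale))
  if (length(bad)) {
    stop_tcrc("tcrcfda_invalid_design", "tau_scale missing level(s): %s",
              paste(bad, collapse = ", "))
  }
  mu_all <- default_mean_curves(grid)
  mu <- mu_all[c(levels_used, "none")]

  groups <- names(design$groups)
  G <- length(groups)
  delta <- array(0, dim = c(G, length(levels_used), n_fpc),
                 dimnames = list(groups, levels_used, NULL))
  if (margin != 0 && n_fpc >= 1) {
    ang <- 2 * pi * (seq_len(G) - 1) / max(G, 2)
    dir <- cbind(cos(ang), sin(ang))
    for (g in seq_len(G)) for (ti in seq_along(levels_used)) {
      lam <- lambda_B * tau_scale[[levels_used[ti]]]
      for (k in seq_len(min(2L, n_fpc))) {
        delta[g, ti, k] <- margin * sqrt(lam[k]) * dir[g, k]
      }
    }
  }
  # Within-bin dose perturbation used by the "unbinned" generator mode: each
  # concentration index gets its own mean, similar within a bin and distinct
  # across bins (the binning stage then has something to discover).
  bump <- sin(pi * x)
  obj <- structure(list(
    grid = grid, mu = mu, phi_B = phi_B,
    lambda_B = lapply(stats::setNames(levels_used, levels_used),
                      function(l) lambda_B * tau_scale[[l]]),
    phi_E = phi_E, lambda_E = lambda_E, sigma2 = sigma2,
    delta = delta, margin = margin, bump = bump,
    bin_map = design$bin_map
  ), class = "truth_model")
  validate_truth_model(obj, w)
  obj
}

#' Validate a truth model's invariants
#'
#' Eigenfunctions quadrature-orthonormal (Gram matrix = identity within
#' 1e-8), eigenvalues nonincreasing and nonnegative, noise variance
#' nonnegative, and all mean functions equal to 1 at the first grid point.
#'
#' @param truth A [make_truth()] object.
#' @param w Optional quadrature weights (recomputed if missing).
#' @return `truth`, invisibly.
#' @export
validate_truth_model <- function(truth, w = NULL) {
  if (is.null(w)) w <- trapezoid_weights(truth$grid)
  for (Phi in list(truth$phi_B, truth$phi_E)) {
    G <- crossprod(Phi, w * Phi)
    if (max(abs(G - diag(ncol(Phi)))) > 1e-8) {
      stop_tcrc("tcrcfda_invalid_truth", "eigenfunctions not quadrature-orthonormal")
    }
  }
  for (lam in c(truth$lambda_B, list(truth$lambda_E))) {
    if (any(lam < 0) || is.unsorted(rev(lam))) {
      stop_tcrc("tcrcfda_invalid_truth", "eigenvalues must be nonincreasing and >= 0")
    }
  }
  if (truth$sigma2 < 0) stop_tcrc("tcrcfda_invalid_truth", "sigma2 must be >= 0")
  for (m in truth$mu) {
    if (abs(m[1] - 1) > 1e-12) {
      stop_tcrc("tcrcfda_invalid_truth", "mean functions must equal 1 at the first grid point")
    }
  }
  invisible(truth)
}

#' Simulate a TCRC panel from a truth model
#'
#' Draws curves from the functional mixed-effects generative model: for
#' chemical c in MOA group g, binned level \eqn{\tau}, replicate o,
#' \deqn{Y(t) = \mu_\tau(t) + \sum_k (\delta_{g\tau k} + b_{\tau c k})
#'   \phi_{B,\tau,k}(t) + \sum_k e_{cok} \phi_{E,k}(t) + \epsilon(t),}
#' with chemical scores \eqn{b \sim N(0, \lambda_B)} shared by all
#' concentration indices mapped to the same bin (those curves are treated as
#' replicates of the binned dose), curve-specific smooth-error scores
#' \eqn{e \sim N(0, \lambda_E)}, and iid white noise
#' \eqn{\epsilon(t) \sim N(0, \sigma^2)} at each grid point. Control curves
#' are \eqn{\mu_{none}} plus smooth error and noise.
#'
#' In `mode = "unbinned"` each concentration index keeps its own mean (the
#' bin mean plus a small within-bin dose perturbation) and `binned_level` is
#' left `NA`, so the binning stage can be exercised against the planted
#' partition (stored in `attr(panel, "true_bin_map")`).
#'
#' @param truth A [make_truth()] object.
#' @param design A [simulation_design()].
#' @param seed Integer seed; panels are bit-identical for identical seeds.
#' @param mode `"binned"` (default) or `"unbinned"`.
#' @param dose_shift Magnitude of the within-bin per-concentration mean
#'   perturbation in unbinned mode.
#' @return A [curve_panel()] with `attr(panel, "truth_scores")` holding the
#'   true per-(chemical, level) scores \eqn{\delta + b} for recovery tests.
#' @export
simulate_panel <- function(truth, design = simulation_design(), seed = 1L,
                           mode = c("binned", "unbinned"), dose_shift = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "truth_model"), inherits(design, "simulation_design"))
  set.seed(as.integer(seed))
  grid <- design$grid
  T_ <- length(grid)
  levels_used <- names(design$bin_map)
  K <- ncol(truth$phi_B)
  KE <- ncol(truth$phi_E)
  groups <- rep(names(design$groups), times = design$groups)
  n_chem <- length(groups)
  chem_ids <- sprintf("chem%03d", seq_len(n_chem))

  idx2lev <- character(design$concentrations)
  for (l in levels_used) idx2lev[design$bin_map[[l]]] <- l

  n_curves <- n_chem * design$concentrations + design$n_controls
  curves <- matrix(NA_real_, n_curves, T_)
  info <- data.frame(chemical_id = character(n_curves), moa_label = NA_character_,
                     concentration_index = NA_integer_, binned_level = NA_character_,
                     replicate_index = NA_integer_, stringsAsFactors = FALSE)
  scores <- vector("list", n_chem)
  row <- 0L
  for (c in seq_len(n_chem)) {
    g <- groups[c]
    b <- lapply(stats::setNames(levels_used, levels_used), function(l)
      stats::rnorm(K, 0, sqrt(truth$lambda_B[[l]])))
    tot <- lapply(stats::setNames(levels_used, levels_used), function(l)
      truth$delta[g, l, ] + b[[l]])
    scores[[c]] <- data.frame(
      chemical_id = chem_ids[c], moa_label = g,
      level = rep(levels_used, each = K), k = rep(seq_len(K), length(levels_used)),
      score = unlist(tot, use.names = FALSE), b = unlist(b, use.names = FALSE),
      stringsAsFactors = FALSE)
    for (ci in seq_len(design$concentrations)) {
      l <- idx2lev[ci]
      mu <- truth$mu[[l]]
      if (mode == "unbinned") {
        pos <- match(ci, design$bin_map[[l]]) - (length(design$bin_map[[l]]) + 1) / 2
        mu <- mu + dose_shift * pos * truth$bump
      }
      e <- stats::rnorm(KE, 0, sqrt(truth$lambda_E))
      y <- mu + truth$phi_B %*% tot[[l]] + truth$phi_E %*% e +
        stats::rnorm(T_, 0, sqrt(truth$sigma2))
      row <- row + 1L
      curves[row, ] <- y
      info$chemical_id[row] <- chem_ids[c]
      info$moa_label[row] <- g
      info$concentration_index[row] <- ci
      info$binned_level[row] <- if (mode == "binned") l else NA_character_
      info$replicate_index[row] <- match(ci, design$bin_map[[l]])
    }
  }
  for (j in seq_len(design$n_controls)) {
    e <- stats::rnorm(KE, 0, sqrt(truth$lambda_E))
    y <- truth$mu[["none"]] + truth$phi_E %*% e + stats::rnorm(T_, 0, sqrt(truth$sigma2))
    row <- row + 1L
    curves[row, ] <- y
    info$chemical_id[row] <- sprintf("control%02d", j)
    info$binned_level[row] <- "none"
    info$replicate_index[row] <- j
  }
  panel <- curve_panel(grid, curves, info, scale = "nci")
  attr(panel, "truth_scores") <- do.call(rbind, scores)
  if (mode == "unbinned") attr(panel, "true_bin_map") <- design$bin_map
  panel
}
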