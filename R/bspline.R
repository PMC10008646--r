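#' Cubic B-spline basis on the experiment time span
#'
#' Builds `n_basis` B-splines of the given degree on `domain` with an open
#' uniform knot vector. The default — 4 cubic B-splines — has no interior
#' knots (`n_basis - degree - 1 = 0`), i.e. the Bernstein-type cubic basis:
#' the only standard construction yielding exactly four cubic B-splines on
#' one interval. An alternative mode places equally spaced interior knots
#' and keeps all resulting basis functions (`n_basis > degree + 1`).
#'
#' The basis satisfies partition of unity (rows sum to 1) and endpoint
#' interpolation (first function is 1 at the left end, last is 1 at the
#' right end).
#'
#' @param domain Length-2 numeric, default `c(0, 72)` hours.
#' @param n_basis Number of basis functions (>= degree + 1).
#' @param degree Polynomial degree (default cubic).
#' @param grid Evaluation grid within `domain`.
#' @return Object of class `bspline_basis`: `knots`, `degree`, `grid`, and
#'   the basis matrix `B` (length(grid) x n_basis).
#' @export
make_bspline_basis <- function(domain = c(0, 72), n_basis = 4L, degree = 3L,
                               grid = seq(1, 72)) {
  if (n_basis < degree + 1L) {
    stop_tcrc("tcrcfda_config_error", "n_basis (%d) must be >= degree + 1 (%d)",
              n_basis, degree + 1L)
  }
  n_interior <- n_basis - degree - 1L
  interior <- if (n_interior > 0) {
    seq(domain[1], domain[2], length.out = n_interior + 2L)[-c(1, n_interior + 2L)]
  } else numeric(0)
  knots <- c(rep(domain[1], degree + 1L), interior, rep(domain[2], degree + 1L))
  B <- splines::splineDesign(knots, x = grid, ord = degree + 1L)
  structure(list(knots = knots, degree = degree, grid = as.numeric(grid), B = B),
            class = "bspline_basis")
}

#' Stack a binned panel into the B-spline mixed-model design
#'
#' Vectorizes the curves over (time, replicate, level) per chemical and
#' attaches the design columns of the multivariate linear mixed model: the
#' response centred by the global pointwise mean over all chemical curves,
#' fixed-effect columns for every (level x spline) combination — crossed
#' with MOA group when `with_groups` — and grouping factors for the
#' chemical-level random coefficients (4 per level per chemical) and the
#' curve-level replicate coefficients (4 per curve).
#'
#' @param panel A binned [curve_panel()]; control curves are excluded (the
#'   model describes treated chemicals).
#' @param basis A [make_bspline_basis()] on the panel grid.
#' @param with_groups Cross fixed effects with the MOA group label.
#' @return Object of class `lmm_design`: long `data`, `X` fixed-effect
#'   matrix, `mu_hat` global mean curve, `levels`, `groups`, `basis`.
#' @export
build_design <- function(panel, basis, with_groups = FALSE) {
  stopifnot(inherits(panel, "curve_panel"), inherits(basis, "bspline_basis"))
  if (!isTRUE(all.equal(basis$grid, panel$grid))) {
    stop_tcrc("tcrcfda_contract_error", "basis grid does not match panel grid")
  }
  lev <- panel$info$binned_level
  if (any(is.na(lev))) {
    stop_tcrc("tcrcfda_contract_error", "panel must be binned before building the design")
  }
  treated <- which(lev != "none")
  if (!length(treated)) stop_tcrc("tcrcfda_contract_error", "no treated curves")
  info <- panel$info[treated, , drop = FALSE]
  curves <- panel$curves[treated, , drop = FALSE]
  if (with_groups && any(is.na(info$moa_label))) {
    stop_tcrc("tcrcfda_contract_error", "with_groups requires MOA labels on all treated curves")
  }
  mu_hat <- colMeans(curves)
  T_ <- length(panel$grid)
  n_curve <- nrow(curves)
  K <- ncol(basis$B)
  levels_used <- intersect(c("high", "medium", "low"), unique(info$binned_level))
  levels_used <- c(levels_used, setdiff(unique(info$binned_level), levels_used))
  ord <- order(match(info$binned_level, levels_used), info$chemical_id,
               info$replicate_index)
  info <- info[ord, , drop = FALSE]
  curves <- curves[ord, , drop = FALSE]
  d <- data.frame(
    y = as.vector(t(sweep(curves, 2, mu_hat))),
    t = rep(panel$grid, n_curve),
    chemical = rep(info$chemical_id, each = T_),
    curve = rep(sprintf("%s.%s.r%d", info$chemical_id, info$binned_level,
                        info$replicate_index), each = T_),
    level = rep(info$binned_level, each = T_),
    group = rep(info$moa_label, each = T_),
    stringsAsFactors = FALSE
  )
  Brep <- basis$B[rep(seq_len(T_), n_curve), , drop = FALSE]
  for (i in seq_len(K)) d[[paste0("s", i)]] <- Brep[, i]
  for (l in levels_used) for (i in seq_len(K)) {
    d[[paste0(l, "_s", i)]] <- Brep[, i] * (d$level == l)
  }
  groups <- if (with_groups) sort(unique(info$moa_label)) else NULL
  fixed_cols <- character(0)
  if (with_groups) {
    for (l in levels_used) for (g in groups) for (i in seq_len(K)) {
      nm <- paste0("fx_", l, "_", g, "_s", i)
      d[[nm]] <- Brep[, i] * (d$level == l) * (d$group == g)
      fixed_cols <- c(fixed_cols, nm)
    }
  } else {
    for (l in levels_used) for (i in seq_len(K)) {
      nm <- paste0("fx_", l, "_s", i)
      d[[nm]] <- d[[paste0(l, "_s", i)]]
      fixed_cols <- c(fixed_cols, nm)
    }
  }
  structure(list(data = d, fixed_cols = fixed_cols, mu_hat = mu_hat,
                 levels = levels_used, groups = groups, basis = basis,
                 n_basis = K, grid = panel$grid, with_groups = with_groups),
            class = "lmm_design")
}

lmm_formula <- function(design) {
  K <- design$n_basis
  rnd_chem <- vapply(design$levels, function(l)
    sprintf("(0 + %s | chemical)",
            paste0(l, "_s", seq_len(K), collapse = " + ")), character(1))
  rnd_curve <- sprintf("(0 + %s | curve)", paste0("s", seq_len(K), collapse = " + "))
  stats::as.formula(paste(
    "y ~ 0 +", paste(design$fixed_cols, collapse = " + "), "+",
    paste(rnd_chem, collapse = " + "), "+", rnd_curve))
}

#' REML fit of the B-spline multivariate linear mixed model
#'
#' Maximizes the REML criterion over the variance components — an
#' unstructured 4 x 4 covariance block per binned level for the chemical
#' coefficients, one unstructured 4 x 4 block for the curve (replicate)
#' coefficients, and a scalar residual variance — returning generalized
#' least-squares fixed effects and BLUP random-effect predictions at the
#' optimum. Estimation is delegated to [lme4::lmer()]; the fit is
#' deterministic given starting values.
#'
#' @param design A [build_design()] object.
#' @param tol Convergence tolerance forwarded to the optimizer.
#' @param start Optional variance-parameter start values (warm start, e.g.
#'   `getME(prev, "theta")` from a previous fit of the same structure).
#' @return Object of class `bspline_fit`: `beta` (fixed effects), `vcov_beta`,
#'   `varcomp` (named list of covariance blocks and `sigma2`), `u`
#'   (chemical-level BLUPs), `w` (curve-level BLUPs), `reml` criterion,
#'   `df_residual`, `converged`, `messages`, and the underlying `merMod`.
#' @export
fit_lmm <- function(design, tol = 1e-8, start = NULL) {
  stopifnot(inherits(design, "lmm_design"))
  if (length(unique(design$data$chemical)) < 2L) {
    stop_tcrc("tcrcfda_contract_error", "at least 2 chemicals are required")
  }
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE, check.conv.singular = "ignore",
    optCtrl = list(FtolAbs = tol, FtolRel = tol, XtolRel = tol))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(lmm_formula(design), data = design$data, REML = TRUE,
               control = ctrl, start = start),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  vc <- lme4::VarCorr(fit)
  varcomp <- lapply(vc, function(m) {
    a <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
    attr(a, "stddev") <- NULL
    a
  })
  names(varcomp) <- vapply(names(vc), function(nm) {
    if (nm == "curve" || startsWith(nm, "curve.")) "G_curve"
    else paste0("G_", sub("_s1.*$", "", rownames(vc[[nm]])[1]))
  }, character(1))
  varcomp$sigma2 <- stats::sigma(fit)^2
  re <- lme4::ranef(fit, condVar = FALSE)
  u <- do.call(cbind, unname(re[names(re) != "curve" &
                                  vapply(re, function(r) !is.null(r), logical(1))]))
  u <- u[, order(match(sub("_s[0-9]+$", "", colnames(u)), design$levels),
                 colnames(u)), drop = FALSE]
  beta <- lme4::fixef(fit)
  structure(list(
    beta = beta, vcov_beta = as.matrix(stats::vcov(fit)), varcomp = varcomp,
    u = u, w = re$curve, reml = as.numeric(lme4::REMLcrit(fit)),
    df_residual = nrow(design$data) - length(beta),
    converged = is.null(fit@optinfo$conv$lme4$code) ||
      fit@optinfo$conv$lme4$code >= 0,
    messages = msgs, design = design, mer = fit
  ), class = "bspline_fit")
}

#' @export
print.bspline_fit <- function(x, ...) {
  cat(sprintf("bspline_fit: %d fixed effects, %d chemicals, REML = %.2f\n",
              length(x$beta), nrow(x$u), x$reml))
  cat(sprintf("  residual sigma2 = %.4g%s\n", x$varcomp$sigma2,
              if (length(x$messages)) sprintf(" [%d optimizer note(s)]",
                                              length(x$messages)) else ""))
  invisible(x)
}

#' MOA-group contrasts of B-spline coefficients with BY control
#'
#' For each (level, spline) pair, tests the difference between the two MOA
#' groups' fixed B-spline coefficients (second group minus first, in sorted
#' group order): Wald estimate, standard error from the fixed-effect
#' covariance, `t = estimate / SE`, two-sided p-value on residual degrees of
#' freedom, and the Benjamini-Yekutieli step-up decision at false discovery
#' rate `q` over all contrasts jointly. BY is used rather than
#' Benjamini-Hochberg because the contrasts are not independent of each
#' other; it inflates the BH thresholds by \eqn{c(m) = \sum_{j=1}^m 1/j} and
#' is therefore valid under arbitrary dependence (and uniformly more
#' conservative).
#'
#' @param fit A [fit_lmm()] result from a design built `with_groups`.
#' @param q False discovery rate level (default 0.1).
#' @return Data frame: `level`, `spline`, `estimate`, `se`, `t`, `p`,
#'   `p_by`, `significant`.
#' @export
group_contrasts <- function(fit, q = 0.1) {
  stopifnot(inherits(fit, "bspline_fit"))
  design <- fit$design
  if (!design$with_groups) {
    stop_tcrc("tcrcfda_contract_error", "fit was built without group effects")
  }
  if (length(design$groups) != 2L) {
    stop_tcrc("tcrcfda_unsupported_design", "exactly 2 groups required, got %d",
              length(design$groups))
  }
  g1 <- design$groups[1]; g2 <- design$groups[2]
  K <- design$n_basis
  rows <- list()
  for (l in design$levels) for (i in seq_len(K)) {
    n1 <- paste0("fx_", l, "_", g1, "_s", i)
    n2 <- paste0("fx_", l, "_", g2, "_s", i)
    L <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
    L[n2] <- 1; L[n1] <- -1
    est <- sum(L * fit$beta)
    se <- sqrt(as.numeric(t(L) %*% fit$vcov_beta %*% L))
    rows[[length(rows) + 1L]] <- data.frame(
      level = l, spline = i, estimate = est, se = se, t = est / se,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p <- 2 * stats::pt(-abs(out$t), df = fit$df_residual)
  out$p_by <- stats::p.adjust(out$p, method = "BY")
  out$significant <- out$p_by <= q
  attr(out, "q") <- q
  attr(out, "contrast") <- sprintf("%s - %s", g2, g1)
  out
}

#' Predict a chemical's TCRC at a binned level
#'
#' Reconstructs the curve from the fitted model without replication effects:
#' \eqn{\hat\mu + \Phi(\hat\beta_\tau + \hat u_{\tau c})}, i.e. global mean
#' plus the level's fixed spline coefficients (for the chemical's group,
#' when the model has group effects) plus the chemical's BLUP coefficients.
#'
#' @param fit A [fit_lmm()] result.
#' @param chemical Chemical id present in the fit.
#' @param level Binned level name.
#' @return Numeric predicted curve on the panel grid.
#' @export
predict_tcrc <- function(fit, chemical, level) {
  stopifnot(inherits(fit, "bspline_fit"))
  design <- fit$design
  if (!chemical %in% rownames(fit$u)) {
    stop_tcrc("tcrcfda_lookup_error", "unknown chemical '%s'", chemical)
  }
  if (!level %in% design$levels) {
    stop_tcrc("tcrcfda_lookup_error", "unknown level '%s'", level)
  }
  K <- design$n_basis
  if (design$with_groups) {
    g <- unique(design$data$group[design$data$chemical == chemical])
    beta_names <- paste0("fx_", level, "_", g, "_s", seq_len(K))
  } else {
    beta_names <- paste0("fx_", level, "_s", seq_len(K))
  }
  beta_tau <- fit$beta[beta_names]
  u_tau <- as.numeric(fit$u[chemical, paste0(level, "_s", seq_len(K))])
  as.numeric(design$mu_hat + design$basis$B %*% (beta_tau + u_tau))
}
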