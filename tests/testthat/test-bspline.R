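test_that("the default basis is a partition of unity with endpoint interpolation", {
  basis <- make_bspline_basis(c(0, 72), grid = seq(0, 72, by = 0.5))
  expect_lt(max(abs(rowSums(basis$B) - 1)), 1e-10)
  expect_true(all(basis$B >= -1e-12))
  expect_equal(basis$B[1, ], c(1, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(basis$B[nrow(basis$B), ], c(0, 0, 0, 1), ignore_attr = TRUE)
  expect_error(make_bspline_basis(c(0, 72), n_basis = 3, degree = 3),
               class = "tcrcfda_config_error")
})

test_that("the basis Gram matrix matches the numeric-integration oracle", {
  basis <- make_bspline_basis(c(0, 72))
  bfun <- function(t, i) splines::splineDesign(basis$knots, t, ord = 4)[, i]
  gram_num <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    gram_num[i, j] <- stats::integrate(function(t) bfun(t, i) * bfun(t, j),
                                       0, 72, rel.tol = 1e-12)$value
  }
  # closed form for the cubic Bernstein basis on [0, L]:
  # int b_i b_j = L * C(3,i) C(3,j) / (7 C(6,i+j))
  gram_exact <- outer(0:3, 0:3, function(i, j)
    72 * choose(3, i) * choose(3, j) / (7 * choose(6, i + j)))
  expect_equal(gram_num, gram_exact, tolerance = 1e-8)
})

test_that("interior-knot bases keep partition of unity", {
  basis <- make_bspline_basis(c(0, 72), n_basis = 7, degree = 3,
                              grid = seq(0, 72, by = 1))
  expect_equal(ncol(basis$B), 7L)
  expect_lt(max(abs(rowSums(basis$B) - 1)), 1e-10)
  expect_equal(basis$knots[5:7], c(18, 36, 54))
})

test_that("the stacked design has the dimensions the replicate counts imply", {
  des <- simulation_design(groups = c(g1 = 1L), concentrations = 11L,
                           n_controls = 0L, grid = 1:72)
  p <- simulate_panel(make_truth(des), des, seed = 1)
  basis <- make_bspline_basis(c(0, 72), grid = 1:72)
  d <- build_design(p, basis)
  expect_equal(nrow(d$data), 792L)             # 72 x (4 + 4 + 3)
  expect_equal(length(unique(d$data$curve)) * 4L, 44L)  # curve-level columns
  expect_equal(length(d$fixed_cols), 12L)      # 3 levels x 4 splines
  # centering: the pointwise mean over curves of the centred response is 0
  bar <- tapply(d$data$y, d$data$t, mean)
  expect_lt(max(abs(bar)), 1e-10)
})

test_that("group designs cross level and spline effects with the groups", {
  fx <- bspline_panel(n_per_group = 2L, levels = c("high", "medium", "low"),
                      seed = 3)
  d <- build_design(fx$panel, fx$basis, with_groups = TRUE)
  expect_equal(length(d$fixed_cols), 24L)      # 2 x 3 x 4
  expect_error(build_design(
    simulate_panel(make_truth(small_design()), small_design(), 1,
                   mode = "unbinned"), fx$basis),
    class = "tcrcfda_contract_error")
})

test_that("REML recovers planted fixed effects in the noiseless limit", {
  fx <- bspline_panel(n_per_group = 3L, levels = c("high", "medium", "low"),
                      beta_diff = c(0, -0.8, 0.6, 0.4),
                      sd_u = 0, sd_w = 0, sigma = 1e-4, seed = 10)
  d <- build_design(fx$panel, fx$basis, with_groups = TRUE)
  fit <- fit_lmm(d)
  # the response is centred by the pointwise grand mean, so the identified
  # fixed effects are the planted coefficients minus their grand average
  diff <- c(0, -0.8, 0.6, 0.4)
  planted <- list()
  for (l in c("high", "medium", "low")) {
    planted[[paste0(l, "_group1")]] <- fx$beta[[l]]
    planted[[paste0(l, "_group10")]] <- fx$beta[[l]] + diff
  }
  beta_bar <- Reduce(`+`, planted) / length(planted)
  for (nm in names(planted)) for (i in 1:4) {
    expect_equal(unname(fit$beta[paste0("fx_", sub("_", "_", nm), "_s", i)]),
                 planted[[nm]][i] - beta_bar[i], tolerance = 1e-3)
  }
  # the group contrast equals the planted difference
  ct <- group_contrasts(fit, q = 0.1)
  for (l in c("high", "medium", "low")) for (i in 1:4) {
    est <- ct$estimate[ct$level == l & ct$spline == i]
    expect_equal(est, c(0, -0.8, 0.6, 0.4)[i], tolerance = 1e-3)
  }
})

test_that("contrast t statistics are estimate over standard error", {
  fx <- bspline_panel(n_per_group = 3L, beta_diff = c(0, 0.5, 0, 0), seed = 21)
  fit <- fit_lmm(build_design(fx$panel, fx$basis, with_groups = TRUE))
  ct <- group_contrasts(fit)
  expect_equal(abs(ct$t), abs(ct$estimate / ct$se), tolerance = 1e-10)
  # BY decisions are monotone in the raw p-values
  ord <- order(ct$p)
  expect_true(all(diff(ct$significant[ord]) <= 0))
  # BY rejections are a subset of BH rejections at the same q
  bh <- stats::p.adjust(ct$p, "BH") <= 0.1
  expect_true(all(!ct$significant | bh))
})

test_that("fixed effects at the optimum equal the GLS closed form", {
  fx <- bspline_panel(n_per_group = 2L, grid = seq(6, 72, by = 6), n_conc = 2L,
                      seed = 31)
  d <- build_design(fx$panel, fx$basis, with_groups = TRUE)
  fit <- fit_lmm(d)
  dd <- d$data
  X <- as.matrix(dd[d$fixed_cols])
  n <- nrow(dd)
  V <- diag(fit$varcomp$sigma2, n)
  Zc <- as.matrix(dd[paste0("high_s", 1:4)])
  for (ch in unique(dd$chemical)) {
    sel <- dd$chemical == ch
    V[sel, sel] <- V[sel, sel] +
      Zc[sel, ] %*% fit$varcomp$G_high %*% t(Zc[sel, ])
  }
  Zw <- as.matrix(dd[paste0("s", 1:4)])
  for (cu in unique(dd$curve)) {
    sel <- dd$curve == cu
    V[sel, sel] <- V[sel, sel] +
      Zw[sel, ] %*% fit$varcomp$G_curve %*% t(Zw[sel, ])
  }
  Vi <- solve(V)
  beta_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% dd$y)
  expect_equal(unname(fit$beta[d$fixed_cols]), as.numeric(beta_gls),
               tolerance = 1e-5)
})

test_that("predicted curves drop replication effects and respect symmetry", {
  # fixed-effects-only data in the spline span: every replicate equals the
  # cell curve, u-hat vanishes, and the prediction is the replicate average
  fx <- bspline_panel(n_per_group = 2L, levels = c("high", "medium", "low"),
                      sd_u = 0, sd_w = 0, sigma = 1e-5, seed = 12)
  d <- build_design(fx$panel, fx$basis, with_groups = TRUE)
  fit <- fit_lmm(d)
  rows <- which(fx$panel$info$chemical_id == "chem01" &
                  fx$panel$info$binned_level == "high")
  avg <- colMeans(fx$panel$curves[rows, , drop = FALSE])
  pred <- predict_tcrc(fit, "chem01", "high")
  expect_equal(pred, avg, tolerance = 1e-4, ignore_attr = TRUE)
  # for a u = 0 chemical the prediction is mu-hat + Phi beta-hat of its group
  beta_g1 <- fit$beta[paste0("fx_high_group1_s", 1:4)]
  expect_equal(pred, as.numeric(d$mu_hat + fx$basis$B %*% beta_g1),
               tolerance = 1e-4)
  expect_error(predict_tcrc(fit, "nope", "high"), class = "tcrcfda_lookup_error")
  expect_error(predict_tcrc(fit, "chem01", "nope"), class = "tcrcfda_lookup_error")
})

test_that("predictions are invariant to replicate relabeling", {
  fx <- bspline_panel(n_per_group = 2L, sd_u = 0.3, sd_w = 0.15, sigma = 0.1,
                      seed = 13)
  fit <- fit_lmm(build_design(fx$panel, fx$basis, with_groups = TRUE))
  info2 <- fx$panel$info
  swap <- info2$chemical_id == "chem01" & info2$binned_level == "high"
  info2$replicate_index[swap] <- rev(info2$replicate_index[swap])
  p2 <- curve_panel(fx$panel$grid, fx$panel$curves, info2)
  fit2 <- fit_lmm(build_design(p2, fx$basis, with_groups = TRUE))
  # agreement is limited by the optimizer stopping rule, not the model:
  # reordering rows moves the REML optimum search path slightly
  expect_equal(predict_tcrc(fit2, "chem01", "high"),
               predict_tcrc(fit, "chem01", "high"), tolerance = 2e-3)
})

test_that("contrasts require a two-group design", {
  fx <- bspline_panel(n_per_group = 2L, seed = 2)
  fit <- fit_lmm(build_design(fx$panel, fx$basis, with_groups = FALSE))
  expect_error(group_contrasts(fit), class = "tcrcfda_contract_error")
})
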