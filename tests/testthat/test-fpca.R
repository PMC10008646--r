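# Hand-assembled fPCA model pieces used by the closed-form BLUP checks.
toy_fpc_model <- function(grid, phi, lambda, sigma2, mu = NULL,
                          phi_E = NULL, lambda_E = numeric(0)) {
  T_ <- length(grid)
  if (is.null(mu)) mu <- rep(0, T_)
  if (is.null(phi_E)) phi_E <- matrix(0, T_, 0)
  structure(list(
    means = structure(list(mu = list(high = mu), grid = grid), class = "mean_model"),
    blocks = list(high = list(values = lambda, functions = phi,
                              varprop = lambda / sum(lambda))),
    E = list(values = lambda_E, functions = phi_E,
             varprop = if (length(lambda_E)) lambda_E / sum(lambda_E) else numeric(0)),
    sigma2 = sigma2, grid = grid, n_fpc = ncol(phi)
  ), class = "fpc_model")
}

quad_phi <- function(grid, k = 1) {
  w <- tcrcfda:::trapezoid_weights(grid)
  x <- (grid - grid[1]) / diff(range(grid))
  f <- sin(k * pi * x)
  f / sqrt(sum(w * f^2))
}

test_that("level means average the curves at each level", {
  g <- 1:10
  f <- sin(g / 2)
  panel <- curve_panel(g, rbind(f, f, -f, f),
                       data.frame(chemical_id = c("a", "a", "b", "b"),
                                  binned_level = c("high", "high", "medium", "medium"),
                                  replicate_index = c(1, 2, 1, 2)),
                       scale = "ci")
  mm <- estimate_means(panel)
  expect_equal(mm$mu$high, f, ignore_attr = TRUE)
  # f and -f average to zero
  panel2 <- curve_panel(g, rbind(f, -f),
                        data.frame(chemical_id = c("a", "b"),
                                   binned_level = "high",
                                   replicate_index = 1), scale = "ci")
  expect_equal(estimate_means(panel2)$mu$high, rep(0, 10), ignore_attr = TRUE)
  expect_error(estimate_means(simulate_panel(make_truth(small_design()),
                                             small_design(), 1, mode = "unbinned")),
               class = "tcrcfda_contract_error")
})

test_that("zero residuals give zero covariance surfaces and zero noise", {
  g <- 1:12
  f <- cos(g / 3)
  panel <- curve_panel(g, rbind(f, f, f, f),
                       data.frame(chemical_id = c("a", "a", "b", "b"),
                                  binned_level = "high",
                                  replicate_index = c(1, 2, 1, 2)),
                       scale = "ci")
  cv <- estimate_covariances(panel, estimate_means(panel))
  expect_equal(max(abs(cv$K_B$high)), 0)
  expect_equal(max(abs(cv$K_E)), 0)
  expect_equal(cv$sigma2, 0)
})

test_that("covariance separation needs replicated cells", {
  g <- 1:12
  panel <- curve_panel(g, matrix(rnorm(24), 2),
                       data.frame(chemical_id = c("a", "b"),
                                  binned_level = "high",
                                  replicate_index = 1), scale = "ci")
  expect_error(estimate_covariances(panel, estimate_means(panel)),
               class = "tcrcfda_identifiability_error")
})

test_that("eigendecomposition recovers a planted rank-1 surface", {
  g <- seq(1, 72)
  phi <- quad_phi(g)
  K <- 2 * tcrossprod(phi)
  eg <- eigendecompose(K, g, n_keep = 3)
  expect_length(eg$values, 1L)  # PSD projection drops the null space
  expect_equal(eg$values[1], 2, tolerance = 1e-8)
  w <- tcrcfda:::trapezoid_weights(g)
  expect_gt(abs(sum(w * eg$functions[, 1] * phi)), 0.999)
  # zero surface: nothing retained
  expect_length(eigendecompose(matrix(0, 72, 72), g)$values, 0L)
  expect_error(eigendecompose(matrix(rnorm(144), 12), 1:12),
               class = "tcrcfda_contract_error")
})

test_that("eigen-reconstruction matches a dense solver oracle", {
  set.seed(5)
  g <- 1:30
  A <- matrix(rnorm(900), 30); K <- crossprod(A) / 30  # random PSD surface
  eg <- eigendecompose(K, g, n_keep = 30)
  w <- tcrcfda:::trapezoid_weights(g)
  recon <- eg$functions %*% (eg$values * t(eg$functions))
  # oracle: direct eigendecomposition of the weighted matrix
  sw <- sqrt(w)
  oe <- eigen(K * tcrossprod(sw), symmetric = TRUE)
  orecon <- sweep(sweep(oe$vectors %*% (oe$values * t(oe$vectors)),
                        1, sw, "/"), 2, sw, "/")
  expect_equal(recon, orecon, tolerance = 1e-8)
  # variance proportions nonincreasing, summing to at most 1
  expect_true(all(diff(eg$varprop) <= 1e-12))
  expect_lte(sum(eg$varprop), 1 + 1e-12)
})

test_that("eigenfunction sign gauge makes the mean integral nonnegative", {
  g <- 1:40
  phi <- quad_phi(g)            # positive bump: integral > 0
  eg <- eigendecompose(tcrossprod(phi), g, n_keep = 1)
  w <- tcrcfda:::trapezoid_weights(g)
  expect_gt(sum(w * eg$functions[, 1]), 0)
  eg2 <- eigendecompose(tcrossprod(-phi), g, n_keep = 1)
  expect_gt(sum(w * eg2$functions[, 1]), 0)  # sign fixed regardless of input
})

test_that("BLUP scores are zero for zero residuals and shrink the projection", {
  g <- seq(2, 72, by = 2)
  phi <- cbind(quad_phi(g, 1), quad_phi(g, 2))
  fpc <- toy_fpc_model(g, phi, c(2, 0.5), sigma2 = 0.2)
  mkp <- function(curves, reps) curve_panel(
    g, curves, data.frame(chemical_id = "a", binned_level = "high",
                          replicate_index = reps), scale = "ci")
  z <- predict_scores(mkp(matrix(0, 2, length(g)), 1:2), fpc)
  expect_equal(as.numeric(z[1, c("V1", "V2")]), c(0, 0))
  # single curve: |BLUP| <= |least-squares projection| componentwise
  set.seed(9)
  for (rep in 1:10) {
    r <- rnorm(length(g))
    sc <- predict_scores(mkp(matrix(r, 1), 1L), fpc)
    proj <- solve(crossprod(phi), crossprod(phi, r))
    expect_lte(abs(sc$V1), abs(proj[1]) + 1e-12)
    expect_lte(abs(sc$V2), abs(proj[2]) + 1e-12)
  }
})

test_that("the BLUP tends to the quadrature projection as noise vanishes", {
  g <- seq(1, 72)
  w <- tcrcfda:::trapezoid_weights(g)
  phi <- quad_phi(g)
  lambda <- 2
  fpc <- toy_fpc_model(g, matrix(phi), lambda, sigma2 = 1e-8)
  cc <- 1.37
  curves <- rbind(cc * phi, cc * phi, cc * phi)
  panel <- curve_panel(g, curves,
                       data.frame(chemical_id = "a", binned_level = "high",
                                  replicate_index = 1:3), scale = "ci")
  sc <- predict_scores(panel, fpc)
  # quadrature inner product of the replicate-average residual with phi
  expected <- sum(w * (cc * phi) * phi)
  expect_equal(sc$V1, expected, tolerance = 1e-6)
})

test_that("missing levels yield flagged NA scores, never imputed values", {
  des <- small_design(n1 = 3L, n2 = 3L)
  p <- simulate_panel(make_truth(des), des, seed = 6)
  drop <- which(p$info$chemical_id == "chem001" & p$info$binned_level == "low")
  p2 <- subset_panel(p, -drop)
  fit <- fit_fpca(p2)
  sc <- predict_scores(p2, fit)
  low_cols <- paste0("V", 7:9)[paste0("V", 7:9) %in% names(sc)]
  expect_true(anyNA(sc[sc$chemical_id == "chem001", low_cols]))
  expect_false(anyNA(sc[sc$chemical_id == "chem002", low_cols]))
})

test_that("truncated reconstruction error decreases with retained components", {
  des <- small_design(n1 = 6L, n2 = 6L)
  p <- simulate_panel(make_truth(des), des, seed = 23)
  means <- estimate_means(p)
  cv <- estimate_covariances(p, means)
  res <- tcrcfda:::panel_residuals(p, means)
  rows <- which(p$info$binned_level == "high")
  w <- tcrcfda:::trapezoid_weights(p$grid)
  errs <- vapply(1:4, function(k) {
    eg <- eigendecompose(cv$K_B$high, p$grid, n_keep = k)
    R <- res[rows, , drop = FALSE]
    scores <- R %*% (w * eg$functions)
    sum(((R - scores %*% t(eg$functions))^2) %*% w)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})
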