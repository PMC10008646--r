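test_that("sum-of-squares decomposition is conserved for any partition", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 3), 40)
    labels <- sample(1:4, 40, replace = TRUE)
    ss <- tcrcfda:::cluster_ss(X, labels)
    expect_equal(ss$bss + ss$wss, ss$tss, tolerance = 1e-10)
  }
})

test_that("k-means clustering handles the degenerate and separated regimes", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0, 0.1), 20), matrix(rnorm(40, 10, 0.1), 20))
  truth <- rep(1:2, each = 20)
  one <- kmeans_cluster(X, k = 1, seed = 1)
  expect_equal(one$bss_tss, 0)
  two <- kmeans_cluster(X, k = 2, seed = 1, truth = truth)
  expect_equal(two$ari, 1)
  expect_equal(two$accuracy, 1)
  expect_gt(two$bss_tss, 0.99)
  # duplicated rows get identical labels
  Xd <- rbind(X, X[1, , drop = FALSE])
  lab <- kmeans_cluster(Xd, k = 2, seed = 2)$labels
  expect_equal(lab[41], lab[1])
  expect_error(kmeans_cluster(X, k = 99, seed = 1), class = "tcrcfda_domain_error")
})

test_that("clustering on informative feature subsets is at least as accurate", {
  # separation planted only in columns 2 and 4
  set.seed(8)
  n <- 30
  truth <- rep(1:2, each = n / 2)
  X <- matrix(rnorm(n * 6, 0, 1.2), n)
  X[, 2] <- X[, 2] / 3 + (truth - 1.5) * 4
  X[, 4] <- X[, 4] / 3 + (truth - 1.5) * 4
  full <- kmeans_cluster(X, 2, seed = 5, truth = truth)
  sub <- kmeans_cluster(X[, c(2, 4)], 2, seed = 5, truth = truth)
  expect_gte(sub$ari, full$ari)
})

test_that("match_accuracy maximizes over label matchings", {
  truth <- c(1, 1, 1, 2, 2, 3)
  m <- match_accuracy(truth, truth)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$confusion[upper.tri(m$confusion)] == 0))
  # assigned labels named adversarially: identity matching would score 0
  labels <- c("b", "b", "b", "c", "c", "a")
  expect_equal(match_accuracy(labels, truth)$accuracy, 1)
  # accuracy >= identity matching accuracy in general
  set.seed(2)
  for (rep in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:3, 12, replace = TRUE)
    expect_gte(match_accuracy(a, b)$accuracy, mean(a == b))
  }
  # differing class counts are padded with zero rows/columns
  m2 <- match_accuracy(c(1, 1, 2, 2), c("x", "x", "y", "z"))
  expect_equal(dim(m2$confusion), c(3L, 3L))
  expect_equal(m2$accuracy, 3 / 4)
})

test_that("SOM grid distances honour topology and wrap-around", {
  # toroidal 4 x 1 grid: the ends are adjacent
  D <- som_grid_distances(som_spec(4, 1, structure = "toroidal"))
  expect_equal(D[1, 4], 1)
  expect_equal(D[1, 3], 2)
  Dp <- som_grid_distances(som_spec(4, 1, structure = "planar"))
  expect_equal(Dp[1, 4], 3)
  # hexagonal axial distance: row neighbours at unit distance
  Dh <- som_grid_distances(som_spec(2, 2, topology = "hexagonal"))
  expect_equal(Dh[1, 2], 1)
  expect_equal(max(Dh), 2)  # no pair further than 2 on a 2 x 2 hex patch
})

test_that("neighbourhood kernels are normalized at the winner", {
  expect_equal(tcrcfda:::som_kernel(0, 2, "gaussian"), 1)
  expect_equal(tcrcfda:::som_kernel(0, 0, "gaussian"), 1)
  expect_equal(tcrcfda:::som_kernel(c(0, 1, 2, 3), 2, "bubble"), c(1, 1, 1, 0))
})

test_that("radius-zero bubble SOM reduces to online k-means on separated clouds", {
  set.seed(14)
  X <- rbind(matrix(rnorm(60, 0, 0.05), 30), matrix(rnorm(60, 8, 0.05), 30))
  truth <- rep(1:2, each = 30)
  spec <- som_spec(2, 1, neighbourhood = "bubble", radius = c(0, 0), epochs = 20)
  som <- som_cluster(X, spec, seed = 9, truth = truth)
  km <- kmeans_cluster(X, 2, seed = 9, truth = truth)
  expect_equal(adjusted_rand_index(som$labels, km$labels), 1)
  expect_equal(som$accuracy, 1)
})

test_that("SOM clustering separates groups and reports empty nodes", {
  set.seed(15)
  X <- rbind(matrix(rnorm(40, 0, 0.1), 20), matrix(rnorm(40, 5, 0.1), 20))
  truth <- rep(1:2, each = 20)
  for (topo in c("rectangular", "hexagonal")) for (str in c("planar", "toroidal")) {
    rep_ <- som_cluster(X, som_spec(2, 1, "bubble", topo, str), seed = 3,
                        truth = truth)
    expect_equal(rep_$accuracy, 1)
  }
  # a 5-node map on 2 distinct points leaves nodes empty without failing
  X2 <- rbind(matrix(0, 20, 2), matrix(5, 20, 2))
  rep5 <- som_cluster(X2, som_spec(5, 1, radius = c(0, 0), neighbourhood = "bubble"),
                      seed = 4)
  expect_true(length(rep5$empty_nodes) >= 3)
})

test_that("the SOM parameter sweep covers the full factorial", {
  set.seed(16)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 6, 0.1), 10))
  sw <- som_sweep(X, truth = rep(1:2, each = 10), grids = list(c(2, 1)),
                  seed = 1, epochs = 5)
  expect_equal(nrow(sw), 8L)  # 2 kernels x 2 topologies x 2 structures
  expect_true(all(sw$accuracy >= 0.5))
})
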