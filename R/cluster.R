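#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected pair-counting similarity:
#' `ARI = (Index - Expected) / (Max - Expected)` over the contingency table
#' of the two labelings. When both labelings are trivial (each a single
#' cluster, so the correction term makes the formula 0/0), the convention is
#' ARI = 1 if the labelings induce the same partition and 0 otherwise.
#'
#' @param a,b Vectors of cluster labels, equal length >= 2.
#' @return A value in \[-1, 1\]; 1 iff the partitions coincide.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)) # -0.5
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop_tcrc("tcrcfda_shape_error", "labelings differ in length (%d vs %d)",
              length(a), length(b))
  }
  n <- length(a)
  if (n < 2L) stop_tcrc("tcrcfda_shape_error", "need at least 2 observations")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  expected <- sum_a * sum_b / total
  maxim <- (sum_a + sum_b) / 2
  if (abs(maxim - expected) < .Machine$double.eps * total) {
    # both labelings trivial: fixed degenerate convention
    same <- isTRUE(all.equal(as.integer(factor(a, levels = unique(a))),
                             as.integer(factor(b, levels = unique(b)))))
    return(if (same) 1 else 0)
  }
  (sum_ij - expected) / (maxim - expected)
}

cluster_ss <- function(X, labels) {
  X <- as.matrix(X)
  centre <- colMeans(X)
  tss <- sum(sweep(X, 2, centre)^2)
  wss <- 0
  for (l in unique(labels)) {
    Xi <- X[labels == l, , drop = FALSE]
    wss <- wss + sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  list(tss = tss, wss = wss, bss = tss - wss)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1L))))
}

#' Permutation-matched clustering accuracy and confusion matrix
#'
#' Cluster labels are arbitrary, so accuracy against a reference labeling is
#' the best achievable fraction of agreements over all one-to-one relabelings
#' of the assigned clusters (brute-force maximization; up to 6 classes).
#' The confusion matrix is reported in truth-by-assigned orientation; when
#' the two labelings use different numbers of classes it is padded with zero
#' rows/columns.
#'
#' @param labels Assigned cluster labels.
#' @param truth Reference labels, same length.
#' @return List with `accuracy` (in \[0, 1\]), `confusion`, and the
#'   maximizing `matching` of assigned to truth classes.
#' @export
match_accuracy <- function(labels, truth) {
  if (length(labels) != length(truth)) {
    stop_tcrc("tcrcfda_shape_error", "labels and truth differ in length")
  }
  n <- length(labels)
  tl <- unique(as.character(truth))
  al <- unique(as.character(labels))
  k <- max(length(tl), length(al))
  if (k > 6L) stop_tcrc("tcrcfda_domain_error", "more than 6 classes not supported")
  conf <- matrix(0L, k, k,
                 dimnames = list(truth = c(tl, rep("", k - length(tl))),
                                 assigned = c(al, rep("", k - length(al)))))
  tab <- table(factor(as.character(truth), levels = tl),
               factor(as.character(labels), levels = al))
  conf[seq_along(tl), seq_along(al)] <- tab
  perms <- permutations_of(k)
  agree <- apply(perms, 1, function(p) sum(conf[cbind(p, seq_len(k))]))
  best <- which.max(agree)
  list(accuracy = agree[best] / n, confusion = conf,
       matching = stats::setNames(rownames(conf)[perms[best, ]], colnames(conf)))
}

make_report <- function(X, labels, truth = NULL, extra = list()) {
  ss <- cluster_ss(X, labels)
  rep_ <- list(labels = labels, bss_tss = if (ss$tss > 0) ss$bss / ss$tss else 0,
               tss = ss$tss, wss = ss$wss, bss = ss$bss,
               accuracy = NA_real_, ari = NA_real_, confusion = NULL)
  if (!is.null(truth)) {
    m <- match_accuracy(labels, truth)
    rep_$accuracy <- m$accuracy
    rep_$confusion <- m$confusion
    rep_$ari <- adjusted_rand_index(labels, truth)
  }
  structure(c(rep_, extra), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report: %d observations, %d clusters, BSS/TSS = %.3f\n",
              length(x$labels), length(unique(x$labels)), x$bss_tss))
  if (!is.na(x$accuracy)) {
    cat(sprintf("  accuracy vs truth: %.2f%% | ARI: %.3f\n", 100 * x$accuracy, x$ari))
  }
  invisible(x)
}

#' k-means clustering with restarts and evaluation
#'
#' Lloyd's algorithm (via [stats::kmeans()]) with `n_start` random
#' initializations; the partition with the lowest within-cluster sum of
#' squares is kept. Reported alongside the labels are the
#' between-to-total-sum-of-squares ratio (BSS/TSS) and, when reference
#' labels are supplied, the permutation-matched accuracy, confusion matrix
#' and ARI.
#'
#' @param X Feature matrix (rows = observations). Columns may be selected
#'   upstream to cluster on feature subsets.
#' @param k Number of clusters (`k <= nrow(X)`).
#' @param seed Integer seed; results are deterministic given seed.
#' @param n_start Number of random restarts.
#' @param truth Optional reference labeling for evaluation.
#' @return A `cluster_report`.
#' @export
kmeans_cluster <- function(X, k, seed = 1L, n_start = 100L, truth = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_tcrc("tcrcfda_domain_error", "features must be finite")
  if (k > nrow(X)) {
    stop_tcrc("tcrcfda_domain_error", "k = %d exceeds n = %d observations", k, nrow(X))
  }
  set.seed(as.integer(seed))
  if (k == 1L) {
    labels <- rep(1L, nrow(X))
  } else {
    km <- suppressWarnings(stats::kmeans(X, centers = k, nstart = n_start,
                                         iter.max = 100L, algorithm = "Lloyd"))
    labels <- km$cluster
  }
  make_report(X, labels, truth)
}

#' Self-organizing map settings
#'
#' The SOM exposes the four choices known to drive clustering performance on
#' TCRC features: the neighbourhood kernel (`"gaussian"` or `"bubble"`), the
#' grid topology (`"rectangular"` or `"hexagonal"`), the map structure
#' (`"planar"` or `"toroidal"`), and the grid size. Learning-rate and radius
#' schedules decay linearly over epochs; the radius starts at half the grid
#' diameter and shrinks to 0 (winner-only updates).
#'
#' @param nrows,ncols Node-grid dimensions.
#' @param neighbourhood `"gaussian"` or `"bubble"`.
#' @param topology `"rectangular"` or `"hexagonal"`.
#' @param structure `"planar"` or `"toroidal"`.
#' @param epochs Number of passes through the data.
#' @param alpha Length-2 vector: initial and final learning rate.
#' @param radius Length-2 vector: initial and final neighbourhood radius;
#'   default half the grid diameter down to 0.
#' @return An object of class `som_spec`.
#' @export
som_spec <- function(nrows = 2L, ncols = 1L,
                     neighbourhood = c("gaussian", "bubble"),
                     topology = c("rectangular", "hexagonal"),
                     structure = c("planar", "toroidal"),
                     epochs = 50L, alpha = c(0.05, 0.01), radius = NULL) {
  neighbourhood <- match.arg(neighbourhood)
  topology <- match.arg(topology)
  structure <- match.arg(structure)
  stopifnot(nrows >= 1, ncols >= 1, epochs >= 1, all(alpha > 0), alpha[1] >= alpha[2])
  if (is.null(radius)) radius <- c(sqrt(nrows^2 + ncols^2) / 2, 0)
  stopifnot(length(radius) == 2L, all(radius >= 0), radius[1] >= radius[2])
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 neighbourhood = neighbourhood, topology = topology,
                 structure = structure, epochs = as.integer(epochs),
                 alpha = alpha, radius = radius),
            class = "som_spec")
}

#' Distances between SOM grid nodes
#'
#' Rectangular topology uses Euclidean distance on integer (row, col)
#' coordinates; hexagonal uses the axial offset (hex-lattice) distance.
#' Toroidal maps wrap both axes, so e.g. nodes 1 and 4 of a toroidal 4 x 1
#' grid are neighbours at distance 1.
#'
#' @param spec A [som_spec()].
#' @return Symmetric `nrows*ncols` square matrix of node distances (nodes in
#'   row-major order).
#' @export
som_grid_distances <- function(spec) {
  coords <- expand.grid(col = seq_len(spec$ncols), row = seq_len(spec$nrows))
  coords <- coords[, c("row", "col")]
  n <- nrow(coords)
  shifts <- if (spec$structure == "toroidal") {
    expand.grid(dr = c(-spec$nrows, 0, spec$nrows), dc = c(-spec$ncols, 0, spec$ncols))
  } else data.frame(dr = 0, dc = 0)
  hexdist <- function(r1, c1, r2, c2) {
    # odd-row offset -> axial coordinates, then hex (cube) distance
    q1 <- c1 - floor(r1 / 2); q2 <- c2 - floor(r2 / 2)
    dq <- q1 - q2; dr <- r1 - r2
    (abs(dq) + abs(dr) + abs(dq + dr)) / 2
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    best <- Inf
    for (s in seq_len(nrow(shifts))) {
      r2 <- coords$row[j] + shifts$dr[s]
      c2 <- coords$col[j] + shifts$dc[s]
      d <- if (spec$topology == "hexagonal") {
        hexdist(coords$row[i], coords$col[i], r2, c2)
      } else {
        sqrt((coords$row[i] - r2)^2 + (coords$col[i] - c2)^2)
      }
      best <- min(best, d)
    }
    D[i, j] <- best
  }
  D
}

som_kernel <- function(d, radius, type) {
  if (type == "bubble") as.numeric(d <= radius)
  else if (radius <= 0) as.numeric(d == 0)
  else exp(-d^2 / (2 * radius^2))
}

#' Online Kohonen self-organizing map clustering
#'
#' Competitive learning on a node grid: at each presentation the winning
#' (nearest) node and its grid neighbours move towards the data point,
#' weighted by the neighbourhood kernel of grid distance and the current
#' learning rate. With radius 0 and the bubble kernel only the winner moves,
#' which is exactly online k-means. Cluster labels are the final winning
#' nodes; with the default k x 1 grid the map is a k-cluster partitioner.
#'
#' @param X Feature matrix (rows = observations).
#' @param spec A [som_spec()].
#' @param seed Integer seed (node initialization by sampling data rows, and
#'   presentation order).
#' @param truth Optional reference labeling for evaluation.
#' @return A `cluster_report`; if some nodes end up empty the report carries
#'   `empty_nodes`.
#' @export
som_cluster <- function(X, spec = som_spec(), seed = 1L, truth = NULL) {
  stopifnot(inherits(spec, "som_spec"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_tcrc("tcrcfda_domain_error", "features must be finite")
  n_nodes <- spec$nrows * spec$ncols
  set.seed(as.integer(seed))
  W <- X[sample.int(nrow(X), n_nodes, replace = nrow(X) < n_nodes), , drop = FALSE]
  D <- som_grid_distances(spec)
  steps <- spec$epochs * nrow(X)
  step <- 0L
  for (ep in seq_len(spec$epochs)) {
    for (i in sample.int(nrow(X))) {
      frac <- step / max(steps - 1L, 1L)
      alpha <- spec$alpha[1] + (spec$alpha[2] - spec$alpha[1]) * frac
      radius <- spec$radius[1] + (spec$radius[2] - spec$radius[1]) * frac
      x <- X[i, ]
      d2 <- rowSums(sweep(W, 2, x)^2)
      win <- which.min(d2)
      h <- som_kernel(D[win, ], radius, spec$neighbourhood)
      upd <- which(h > 0)
      W[upd, ] <- W[upd, , drop = FALSE] +
        alpha * h[upd] * (matrix(x, length(upd), ncol(W), byrow = TRUE) -
                            W[upd, , drop = FALSE])
      step <- step + 1L
    }
  }
  labels <- apply(X, 1, function(x) which.min(colSums((t(W) - x)^2)))
  empty <- setdiff(seq_len(n_nodes), unique(labels))
  make_report(X, labels, truth,
              extra = list(nodes = W, empty_nodes = empty, spec = spec))
}

#' Exhaustive SOM parameter sweep
#'
#' Trains a SOM for every combination of neighbourhood kernel, topology,
#' structure and the supplied grid sizes, reporting the permutation-matched
#' accuracy of each configuration against the reference labels.
#'
#' @param X Feature matrix.
#' @param truth Reference labels.
#' @param grids List of `c(nrows, ncols)` pairs.
#' @param seed Integer seed.
#' @param epochs Epochs per configuration.
#' @return Data frame, one row per configuration, with accuracy and BSS/TSS.
#' @export
som_sweep <- function(X, truth, grids = list(c(2, 1)), seed = 1L, epochs = 50L) {
  cfg <- expand.grid(neighbourhood = c("gaussian", "bubble"),
                     topology = c("rectangular", "hexagonal"),
                     structure = c("planar", "toroidal"),
                     grid = seq_along(grids), stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cfg)), function(i) {
    g <- grids[[cfg$grid[i]]]
    spec <- som_spec(g[1], g[2], cfg$neighbourhood[i], cfg$topology[i],
                     cfg$structure[i], epochs = epochs)
    rep_ <- som_cluster(X, spec, seed = seed, truth = truth)
    data.frame(neighbourhood = cfg$neighbourhood[i], topology = cfg$topology[i],
               structure = cfg$structure[i], nrows = g[1], ncols = g[2],
               accuracy = rep_$accuracy, bss_tss = rep_$bss_tss,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
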