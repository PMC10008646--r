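# Shared fixtures, built in code and cached for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# A small but fully structured design: 3 binned levels, 2 concentration
# indices each, a handful of chemicals in two groups, coarse 18-point grid.
small_design <- function(n1 = 5L, n2 = 4L, grid = seq(4, 72, by = 4)) {
  simulation_design(groups = c(group1 = n1, group10 = n2), concentrations = 6L,
                    n_controls = 3L,
                    bin_map = list(high = 1:2, medium = 3:4, low = 5:6),
                    grid = grid)
}

small_panel <- function() {
  with_cache("small_panel", {
    des <- small_design()
    simulate_panel(make_truth(des), des, seed = 402L)
  })
}

# Panel simulated directly from the B-spline mixed model:
# y = mu + B (beta_group + u_chem + w_curve) + noise, used for the
# B-spline module's parameter-recovery and power properties.
bspline_panel <- function(n_per_group = 5L, grid = seq(3, 72, by = 3),
                          levels = "high", n_conc = 3L,
                          beta = NULL, beta_diff = rep(0, 4),
                          sd_u = 0.3, sd_w = 0.15, sigma = 0.1, seed = 1L) {
  set.seed(seed)
  basis <- make_bspline_basis(c(0, 72), grid = grid)
  B <- basis$B
  T_ <- length(grid)
  mu <- 1 + 0.02 * (grid - grid[1])
  if (is.null(beta)) beta <- list(high = c(0, 0.5, -0.5, -1),
                                  medium = c(0, 0.4, 0, -0.3),
                                  low = c(0, 0.3, 0.2, 0))
  n_chem <- 2L * n_per_group
  rows <- list(); info <- list()
  for (c in seq_len(n_chem)) {
    g <- if (c <= n_per_group) "group1" else "group10"
    for (l in levels) {
      u <- rnorm(4, 0, sd_u)
      bl <- beta[[l]] + if (g == "group10") beta_diff else 0
      for (o in seq_len(n_conc)) {
        w <- rnorm(4, 0, sd_w)
        y <- mu + B %*% (bl + u + w) + rnorm(T_, 0, sigma)
        rows[[length(rows) + 1L]] <- as.numeric(y)
        info[[length(info) + 1L]] <- data.frame(
          chemical_id = sprintf("chem%02d", c), moa_label = g,
          concentration_index = o + (match(l, c("high", "medium", "low")) - 1L) * n_conc,
          binned_level = l, replicate_index = o, stringsAsFactors = FALSE)
      }
    }
  }
  list(panel = curve_panel(grid, do.call(rbind, rows), do.call(rbind, info)),
       basis = basis, mu = mu, beta = beta)
}

# Independent pair-counting ARI oracle: loops over all observation pairs.
ari_bruteforce <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) {
    return(if (n10 + n01 == 0) 1 else 0)
  }
  2 * (n11 * n00 - n10 * n01) / den
}

# Expand a confusion matrix (truth x assigned) into label vectors.
labels_from_confusion <- function(conf) {
  truth <- assigned <- character(0)
  for (i in seq_len(nrow(conf))) for (j in seq_len(ncol(conf))) {
    k <- conf[i, j]
    truth <- c(truth, rep(rownames(conf)[i], k))
    assigned <- c(assigned, rep(colnames(conf)[j], k))
  }
  list(truth = truth, assigned = assigned)
}
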