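#' One-way MANOVA on score vectors
#'
#' Tests equality of multivariate group means (e.g. fPCA scores V1..V9
#' between MOA groups) with the four classical statistics — Wilks' Lambda,
#' Pillai's trace, Hotelling-Lawley trace and Roy's largest root — each
#' with its standard approximate-F transformation and p-value (Rao's F for
#' Wilks; the upper-bound F for Roy). With two groups (or one response) the
#' nonzero eigenvalue of \eqn{E^{-1}H} is unique, all four F statistics
#' coincide, and the p-values are exact (flagged in the output).
#'
#' The statistics are computed through [stats::manova()]; this wrapper adds
#' the identifiability checks the raw fit lacks and assembles the combined
#' table.
#'
#' @param X Numeric score matrix, n rows (observations) by p columns.
#' @param groups Group labels, length n, at least 2 groups.
#' @return Object of class `manova_table`: data frame with one row per
#'   statistic (`statistic`, `value`, `approx_f`, `df1`, `df2`, `p`), plus
#'   attributes `exact` and `eigenvalues` (of \eqn{E^{-1}H}).
#' @export
manova_oneway <- function(X, groups) {
  X <- as.matrix(X)
  groups <- factor(groups)
  n <- nrow(X); p <- ncol(X); g <- nlevels(groups)
  if (length(groups) != n) stop_tcrc("tcrcfda_shape_error", "groups length != nrow(X)")
  if (g < 2L) stop_tcrc("tcrcfda_domain_error", "need at least 2 groups")
  if (n <= p + g - 1L) {
    stop_tcrc("tcrcfda_domain_error",
              "n = %d too small for p = %d responses and %d groups", n, p, g)
  }
  # within-group scatter must be nonsingular; name offending columns
  E <- matrix(0, p, p)
  for (l in levels(groups)) {
    Xi <- X[groups == l, , drop = FALSE]
    E <- E + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  qe <- qr(E)
  if (qe$rank < p) {
    bad <- colnames(X)[qe$pivot[(qe$rank + 1L):p]]
    if (is.null(bad)) bad <- as.character(qe$pivot[(qe$rank + 1L):p])
    stop_tcrc("tcrcfda_rank_error",
              "within-group scatter is singular; offending column(s): %s",
              paste(bad, collapse = ", "))
  }
  Xc <- sweep(X, 2, colMeans(X))
  H <- crossprod(Xc) - E
  eigs <- Re(eigen(solve(E, H), only.values = TRUE)$values)
  fit <- stats::manova(X ~ groups)
  tests <- c(Wilks = "Wilks", Pillai = "Pillai",
             `Hotelling-Lawley` = "Hotelling-Lawley", Roy = "Roy")
  rows <- lapply(names(tests), function(nm) {
    st <- summary(fit, test = tests[[nm]])$stats
    data.frame(statistic = nm, value = st[1, 2], approx_f = st[1, 3],
               df1 = st[1, 4], df2 = st[1, 5], p = st[1, 6],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  s <- min(g - 1L, p)
  attr(out, "exact") <- s == 1L
  attr(out, "eigenvalues") <- sort(eigs, decreasing = TRUE)
  class(out) <- c("manova_table", "data.frame")
  out
}

#' @export
print.manova_table <- function(x, ...) {
  cat(sprintf("One-way MANOVA (%s p-values)\n",
              if (isTRUE(attr(x, "exact"))) "exact" else "approximate"))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
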