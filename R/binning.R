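#' Per-chemical wavelet features from concatenated curves
#'
#' Concatenates each chemical's curves in concentration order 1..11 into one
#' long vector and extracts the scaling coefficients of a level-`level` DWT:
#' the whole-chemical feature representation used for wavelet-based MOA
#' clustering.
#'
#' @param panel A [curve_panel()]; every chemical must have the same number
#'   of concentration-indexed curves (controls are ignored).
#' @param level DWT decomposition level.
#' @param wavelet Filter family, see [dwt_scaling_coeffs()].
#' @return Feature matrix with one row per chemical, rownames = chemical id.
#' @export
chemical_wavelet_features <- function(panel, level = 4L, wavelet = "db4") {
  stopifnot(inherits(panel, "curve_panel"))
  keep <- !is.na(panel$info$concentration_index)
  info <- panel$info[keep, , drop = FALSE]
  curves <- panel$curves[keep, , drop = FALSE]
  chems <- unique(info$chemical_id)
  counts <- table(info$chemical_id)
  if (length(unique(as.integer(counts))) != 1L) {
    stop_tcrc("tcrcfda_shape_error",
              "ragged panel: chemicals have differing numbers of curves")
  }
  feats <- lapply(chems, function(ch) {
    rows <- which(info$chemical_id == ch)
    rows <- rows[order(info$concentration_index[rows])]
    dwt_scaling_coeffs(as.vector(t(curves[rows, , drop = FALSE])), level, wavelet)
  })
  out <- do.call(rbind, feats)
  rownames(out) <- chems
  out
}

contiguous_split <- function(n_conc, k_bins) {
  sizes <- rep(n_conc %/% k_bins, k_bins)
  extra <- n_conc %% k_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k_bins), times = sizes)
}

bin_names_for <- function(k_bins) {
  if (k_bins == 3L) c("high", "medium", "low") else paste0("bin", seq_len(k_bins))
}

#' Data-driven binning of concentration levels
#'
#' Reduces the concentration factor from 11 indices to `k_bins` levels. For
#' each concentration index, the chemicals' curves are summarized by DWT
#' scaling coefficients and split into two groups by k-means (restarted,
#' seed-fixed): one binary labeling per index. All pairwise labelings are
#' compared by the Adjusted Rand Index; agglomerative clustering with
#' complete linkage on dissimilarity `1 - ARI`, cut at `k_bins`, groups
#' indices that partition the chemicals the same way. Bins are named by mean
#' concentration index (the bin containing the lowest indices, i.e. the
#' strongest doses, is `"high"`).
#'
#' If all 11 labelings are identical the ARI matrix is all ones and any cut
#' is valid; the binning then falls back to a contiguous index split.
#'
#' @param panel A [curve_panel()] with >= 2 chemicals per concentration.
#' @param k_bins Number of bins (default 3).
#' @param level,wavelet DWT settings, see [dwt_scaling_coeffs()].
#' @param seed Integer seed for the k-means restarts.
#' @param n_start k-means restarts per concentration index.
#' @return An object of class `binning_result`: per-concentration labelings,
#'   the ARI matrix, the `hclust` merge history, the bin assignment map, and
#'   (when MOA labels are present) each labeling's ARI against MOA.
#' @export
bin_concentrations <- function(panel, k_bins = 3L, level = 4L, wavelet = "db4",
                               seed = 1L, n_start = 100L) {
  stopifnot(inherits(panel, "curve_panel"))
  treated <- !is.na(panel$info$concentration_index)
  conc <- sort(unique(panel$info$concentration_index[treated]))
  n_conc <- length(conc)
  labelings <- matrix(NA_integer_, nrow = 0, ncol = 0)
  chems <- unique(panel$info$chemical_id[treated])
  labelings <- matrix(NA_integer_, length(chems), n_conc,
                      dimnames = list(chems, paste0("C", conc)))
  for (j in seq_len(n_conc)) {
    rows <- which(treated & panel$info$concentration_index == conc[j])
    rows <- rows[match(chems, panel$info$chemical_id[rows])]
    if (any(is.na(rows)) || length(rows) < 2L) {
      stop_tcrc("tcrcfda_degenerate_clustering",
                "concentration index %d has fewer curves than clusters", conc[j])
    }
    feats <- t(apply(panel$curves[rows, , drop = FALSE], 1,
                     dwt_scaling_coeffs, level = level, wavelet = wavelet))
    rep_ <- kmeans_cluster(feats, k = 2L, seed = derive_seed(seed, paste0("conc", conc[j])),
                           n_start = n_start)
    labelings[, j] <- rep_$labels
  }
  ari <- diag(1, n_conc)
  dimnames(ari) <- list(colnames(labelings), colnames(labelings))
  for (i in seq_len(n_conc - 1L)) for (j in (i + 1L):n_conc) {
    ari[i, j] <- ari[j, i] <- adjusted_rand_index(labelings[, i], labelings[, j])
  }
  nm <- bin_names_for(k_bins)
  if (all(abs(ari - 1) < 1e-12)) {
    cut <- contiguous_split(n_conc, k_bins)
    hc <- NULL
  } else {
    hc <- stats::hclust(stats::as.dist(1 - ari), method = "complete")
    cut <- stats::cutree(hc, k = k_bins)
  }
  # order bins by mean concentration index: lowest mean index -> strongest dose
  mean_idx <- tapply(conc, cut, mean)
  ord <- order(mean_idx)
  bin_map <- stats::setNames(vector("list", k_bins), nm)
  for (b in seq_len(k_bins)) bin_map[[b]] <- conc[cut == ord[b]]
  moa_ari <- NULL
  moa <- panel$info$moa_label[treated][match(chems, panel$info$chemical_id[treated])]
  if (!all(is.na(moa))) {
    moa_ari <- apply(labelings, 2, adjusted_rand_index, b = moa)
  }
  structure(list(labelings = labelings, ari_matrix = ari, hclust = hc,
                 bin_map = bin_map, moa_ari = moa_ari, k_bins = k_bins),
            class = "binning_result")
}

#' @export
print.binning_result <- function(x, ...) {
  cat("binning_result:\n")
  for (nm in names(x$bin_map)) {
    cat(sprintf("  %-7s <- C%s\n", nm, paste(x$bin_map[[nm]], collapse = ", C")))
  }
  invisible(x)
}

#' Apply a concentration bin map to a panel
#'
#' Sets each treated curve's `binned_level` according to its concentration
#' index under `bin_map`, and renumbers `replicate_index` as the position
#' within the bin (curves from different concentrations in one bin are
#' treated as replicates of the binned dose). Control curves become level
#' `"none"`.
#'
#' @param panel A [curve_panel()].
#' @param bin_map Named list mapping bin names to concentration indices
#'   (e.g. from [bin_concentrations()] or a [simulation_design()]).
#' @return The panel with `binned_level` filled in.
#' @export
apply_binning <- function(panel, bin_map) {
  stopifnot(inherits(panel, "curve_panel"))
  info <- panel$info
  for (nm in names(bin_map)) {
    sel <- info$concentration_index %in% bin_map[[nm]]
    info$binned_level[sel] <- nm
    info$replicate_index[sel] <- match(info$concentration_index[sel],
                                       sort(bin_map[[nm]]))
  }
  info$binned_level[is.na(info$concentration_index)] <- "none"
  curve_panel(panel$grid, panel$curves, info, scale = panel$scale,
              anchored = panel$anchored)
}
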