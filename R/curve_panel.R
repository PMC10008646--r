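#' Curve panels: collections of TCRCs on a common time grid
#'
#' A `curve_panel` is the package's universal interchange object: a set of
#' time-dependent cellular response curves (TCRCs) sampled on one common,
#' strictly increasing time grid (hourly by default, t = 1..72 h after
#' chemical treatment; the pre-treatment anchor point of the normalized cell
#' index is consumed by normalization and not stored). Each curve carries
#' annotations: the chemical it belongs to, an optional mode-of-action (MOA)
#' label, the concentration index 1..11 (1 = strongest dose, `NA` for
#' untreated controls), the binned concentration level
#' (`"high"`/`"medium"`/`"low"`/`"none"`, `NA` until binning has been
#' applied), and a replicate index.
#'
#' @param grid Strictly increasing numeric vector of time points (hours).
#' @param curves Numeric matrix, one row per curve, `length(grid)` columns.
#' @param info Data frame with one row per curve and columns `chemical_id`
#'   (character), `moa_label` (character or `NA`), `concentration_index`
#'   (integer 1..11 or `NA` for controls), `binned_level` (character or `NA`),
#'   `replicate_index` (integer).
#' @param scale `"nci"` for normalized cell index panels, `"ci"` for raw.
#' @param anchored Logical; `TRUE` marks a noise-free NCI panel whose curves
#'   are exactly 1 at the first grid point (enforced by validation).
#' @return An object of class `curve_panel`.
#' @seealso [read_curve_panel()], [simulate_panel()], [apply_binning()]
#' @export
curve_panel <- function(grid, curves, info, scale = "nci", anchored = FALSE) {
  if (is.vector(curves)) curves <- matrix(curves, nrow = 1L)
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  required <- c("chemical_id", "moa_label", "concentration_index",
                "binned_level", "replicate_index")
  for (col in setdiff(required, names(info))) {
    info[[col]] <- if (col %in% c("chemical_id", "moa_label", "binned_level"))
      NA_character_ else NA_integer_
  }
  obj <- structure(
    list(grid = as.numeric(grid), curves = as.matrix(curves),
         info = info[required], scale = scale, anchored = isTRUE(anchored)),
    class = "curve_panel"
  )
  validate_curve_panel(obj)
  obj
}

#' Validate a curve panel's invariants
#'
#' Checks that all curves share the grid, the grid is strictly increasing,
#' concentration indices lie in 1..11 or are `NA` (controls), binned levels
#' are one of high/medium/low/none or `NA`, and — for anchored NCI panels —
#' that every curve equals 1 at the first grid point to within `1e-12`.
#'
#' @param x A [curve_panel()].
#' @return `x`, invisibly; errors on violation.
#' @export
validate_curve_panel <- function(x) {
  stopifnot(inherits(x, "curve_panel"))
  if (length(x$grid) < 2L || any(diff(x$grid) <= 0)) {
    stop_tcrc("tcrcfda_invalid_panel", "grid must be strictly increasing with >= 2 points")
  }
  if (ncol(x$curves) != length(x$grid)) {
    stop_tcrc("tcrcfda_invalid_panel",
              "curves have %d columns but grid has %d points",
              ncol(x$curves), length(x$grid))
  }
  if (nrow(x$curves) != nrow(x$info)) {
    stop_tcrc("tcrcfda_invalid_panel", "info rows (%d) != number of curves (%d)",
              nrow(x$info), nrow(x$curves))
  }
  ci <- x$info$concentration_index
  if (any(!is.na(ci) & (ci < 1 | ci > 11 | ci != round(ci)))) {
    stop_tcrc("tcrcfda_invalid_panel", "concentration_index must be in 1..11 or NA")
  }
  bl <- x$info$binned_level
  if (any(!is.na(bl) & !bl %in% c("high", "medium", "low", "none"))) {
    stop_tcrc("tcrcfda_invalid_panel", "binned_level must be high/medium/low/none or NA")
  }
  if (identical(x$scale, "nci") && x$anchored) {
    if (any(abs(x$curves[, 1] - 1) > 1e-12)) {
      stop_tcrc("tcrcfda_invalid_panel",
                "anchored NCI panel must equal 1 at the first grid point")
    }
  }
  invisible(x)
}

#' @export
print.curve_panel <- function(x, ...) {
  nlev <- sum(!is.na(unique(x$info$binned_level)))
  cat(sprintf("curve_panel: %d curves x %d time points [%g, %g] h (%s scale)\n",
              nrow(x$curves), length(x$grid), min(x$grid), max(x$grid), x$scale))
  cat(sprintf("  chemicals: %d | controls: %d | binned levels present: %d\n",
              length(unique(stats::na.omit(x$info$chemical_id[!is.na(x$info$concentration_index)]))),
              sum(is.na(x$info$concentration_index)), nlev))
  invisible(x)
}

#' @export
plot.curve_panel <- function(x, ..., col = NULL) {
  lev <- x$info$binned_level
  if (is.null(col)) {
    col <- c(high = "firebrick", medium = "goldenrod", low = "forestgreen",
             none = "grey40")[lev]
    col[is.na(col)] <- "steelblue"
  }
  graphics::matplot(x$grid, t(x$curves), type = "l", lty = 1, col = col,
                    xlab = "time after treatment (h)", ylab = "NCI", ...)
  invisible(x)
}

#' Subset a curve panel by curve
#'
#' @param panel A [curve_panel()].
#' @param i Logical or integer index over curves.
#' @return The subset panel.
#' @export
subset_panel <- function(panel, i) {
  stopifnot(inherits(panel, "curve_panel"))
  curve_panel(panel$grid, panel$curves[i, , drop = FALSE],
              panel$info[i, , drop = FALSE], scale = panel$scale,
              anchored = panel$anchored)
}

default_schema <- function() {
  c(chemical_id = "chemical_id", moa_label = "moa",
    concentration_index = "concentration", replicate_index = "replicate",
    time_h = "time_h", value = "value", binned_level = "binned_level")
}

#' Read a curve panel from a long-format CSV file
#'
#' The file must contain one row per (curve, time point) with columns
#' `chemical_id`, `concentration`, `replicate`, `time_h`, `value` and
#' optionally `moa` and `binned_level` (names remappable through `schema`).
#' Curves are sorted by (chemical, concentration, replicate, time). Curves
#' missing some grid time points are not silently padded: they are excluded
#' from the panel matrix and attached, as raw series, under
#' `attr(panel, "pending_interpolation")` for [to_uniform_grid()].
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping panel fields to file column
#'   names; see `tcrcfda:::default_schema()`.
#' @param scale Passed to [curve_panel()].
#' @return A [curve_panel()].
#' @export
read_curve_panel <- function(path, schema = default_schema(), scale = "nci") {
  if (!file.exists(path)) stop_tcrc("tcrcfda_io_error", "file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- schema[c("chemical_id", "concentration_index", "replicate_index",
                   "time_h", "value")]
  missing_cols <- setdiff(unname(need), names(raw))
  if (length(missing_cols)) {
    stop_tcrc("tcrcfda_schema_error", "missing required column(s): %s",
              paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    chemical_id = as.character(raw[[need[["chemical_id"]]]]),
    concentration_index = suppressWarnings(as.integer(raw[[need[["concentration_index"]]]])),
    replicate_index = as.integer(raw[[need[["replicate_index"]]]]),
    time_h = as.numeric(raw[[need[["time_h"]]]]),
    value = as.numeric(raw[[need[["value"]]]]),
    stringsAsFactors = FALSE
  )
  df$moa_label <- if (schema[["moa_label"]] %in% names(raw))
    as.character(raw[[schema[["moa_label"]]]]) else NA_character_
  df$binned_level <- if (schema[["binned_level"]] %in% names(raw))
    as.character(raw[[schema[["binned_level"]]]]) else NA_character_

  key <- paste(df$chemical_id, df$concentration_index, df$replicate_index,
               df$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    stop_tcrc("tcrcfda_integrity_error",
              "duplicate (chemical, concentration, replicate, time) rows in %s", path)
  }
  grid <- sort(unique(df$time_h))
  ckey <- paste(df$chemical_id, df$concentration_index, df$replicate_index, sep = "\r")
  ord <- order(df$chemical_id, df$concentration_index, df$replicate_index, df$time_h)
  df <- df[ord, ]
  ckey <- ckey[ord]
  pieces <- split(df, factor(ckey, levels = unique(ckey)))
  complete <- vapply(pieces, function(p)
    length(p$time_h) == length(grid) && all(p$time_h == grid), logical(1))
  mk_info <- function(p) data.frame(
    chemical_id = p$chemical_id[1], moa_label = p$moa_label[1],
    concentration_index = p$concentration_index[1],
    binned_level = p$binned_level[1], replicate_index = p$replicate_index[1],
    stringsAsFactors = FALSE)
  curves <- do.call(rbind, lapply(pieces[complete], function(p) p$value))
  info <- do.call(rbind, lapply(pieces[complete], mk_info))
  panel <- curve_panel(grid, curves, info, scale = scale)
  if (any(!complete)) {
    pending <- lapply(pieces[!complete], function(p)
      raw_series(p$time_h, p$value, mk_info(p)))
    attr(panel, "pending_interpolation") <- pending
    message(sprintf("%d curve(s) with missing time points flagged for interpolation",
                    length(pending)))
  }
  panel
}

#' Write a curve panel to a long-format CSV file
#'
#' Inverse of [read_curve_panel()]: values are written at full double
#' precision so a write/read round trip is the identity to 1e-12.
#'
#' @param panel A [curve_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_panel <- function(panel, path) {
  stopifnot(inherits(panel, "curve_panel"))
  n <- nrow(panel$curves)
  T_ <- length(panel$grid)
  out <- data.frame(
    chemical_id = rep(panel$info$chemical_id, each = T_),
    moa = rep(panel$info$moa_label, each = T_),
    concentration = rep(panel$info$concentration_index, each = T_),
    binned_level = rep(panel$info$binned_level, each = T_),
    replicate = rep(panel$info$replicate_index, each = T_),
    time_h = rep(panel$grid, times = n),
    value = as.vector(t(panel$curves)),
    stringsAsFactors = FALSE
  )
  write_table(out, path)
}

#' Write a result table as CSV with full floating-point precision
#'
#' @param rows A data frame (scores, contrasts, confusion matrices, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_tcrc("tcrcfda_io_error", "directory does not exist: %s", dir)
  num <- vapply(rows, is.double, logical(1))
  rows[num] <- lapply(rows[num], function(v) {
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- NA_character_
    s
  })
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE, quote = TRUE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_tcrc("tcrcfda_io_error", "cannot write to %s", path)
  invisible(path)
}
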