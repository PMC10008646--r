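#' Pipeline configuration
#'
#' Bundles the tunable settings of the end-to-end TCRC analysis with
#' validation: wavelet family and decomposition level, k-means restarts, SOM
#' settings, number of functional principal components per chemical-effect
#' block, B-spline basis size and degree, the false discovery rate for the
#' group contrasts, and the master random seed (every stochastic stage
#' derives its own seed from it by a fixed stage-name hash, so partial
#' re-runs reproduce the full run).
#'
#' @param wavelet Wavelet family for binning features.
#' @param level DWT decomposition level (>= 1).
#' @param kmeans_restarts Restarts for every k-means call.
#' @param som A [som_spec()].
#' @param n_fpc Chemical-effect components per binned level.
#' @param e_var_threshold Variance threshold for the smooth-error block.
#' @param n_basis,degree B-spline basis settings.
#' @param q FDR level in (0, 1).
#' @param seed Integer master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(wavelet = "db4", level = 4L, kmeans_restarts = 100L,
                            som = som_spec(), n_fpc = 3L, e_var_threshold = 0.95,
                            n_basis = 4L, degree = 3L, q = 0.1, seed = 1L) {
  if (!is.numeric(level) || level < 1 || level != round(level)) {
    stop_tcrc("tcrcfda_config_error", "decomposition level must be an integer >= 1")
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop_tcrc("tcrcfda_config_error", "q must lie in (0, 1)")
  }
  if (!is.numeric(seed) || seed != round(seed)) {
    stop_tcrc("tcrcfda_config_error", "seed must be an integer")
  }
  get_wavelet_filter(wavelet)
  stopifnot(inherits(som, "som_spec"), n_fpc >= 1, kmeans_restarts >= 1)
  structure(list(wavelet = wavelet, level = as.integer(level),
                 kmeans_restarts = as.integer(kmeans_restarts), som = som,
                 n_fpc = as.integer(n_fpc), e_var_threshold = e_var_threshold,
                 n_basis = as.integer(n_basis), degree = as.integer(degree),
                 q = q, seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(stage, fmt = "", ...) {
  message(sprintf("[%s] %s%s", format(Sys.time(), "%H:%M:%S"), stage,
                  if (nzchar(fmt)) paste0(": ", sprintf(fmt, ...)) else ""))
}

run_stage <- function(stage, expr) {
  log_stage(stage)
  tryCatch(expr, error = function(e) {
    stop_tcrc("tcrcfda_stage_error", "stage '%s' failed: %s", stage,
              conditionMessage(e))
  })
}

#' Run the full TCRC analysis pipeline
#'
#' Orchestrates the end-to-end analysis of a curve panel: concentration
#' binning (skipped when the panel is already binned), the fPCA functional
#' mixed model with BLUP score prediction, one-way MANOVA on the scores of
#' the two largest labelled groups, the B-spline mixed model with
#' BY-controlled group contrasts, and k-means plus SOM clustering of the
#' score vectors. All result tables are written as CSV under `out_dir` when
#' given. Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param panel A [curve_panel()] on the NCI scale.
#' @param out_dir Optional output directory for result tables.
#' @return A list bundle: `binning`, `fpca`, `scores`, `manova`, `bspline`,
#'   `contrasts`, `kmeans`, `som`.
#' @export
run_pipeline <- function(config, panel, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"), inherits(panel, "curve_panel"))
  validate_curve_panel(panel)
  bundle <- list()

  binned <- !any(is.na(panel$info$binned_level))
  if (!binned) {
    bundle$binning <- run_stage("binning", bin_concentrations(
      panel, k_bins = 3L, level = config$level, wavelet = config$wavelet,
      seed = derive_seed(config$seed, "binning"), n_start = config$kmeans_restarts))
    panel <- apply_binning(panel, bundle$binning$bin_map)
  }

  bundle$fpca <- run_stage("fpca", fit_fpca(
    panel, n_fpc = config$n_fpc, e_var_threshold = config$e_var_threshold))
  bundle$scores <- run_stage("scores", predict_scores(panel, bundle$fpca))

  moa <- bundle$scores$moa_label
  two <- names(sort(table(moa), decreasing = TRUE))[1:2]
  sel <- !is.na(moa) & moa %in% two & stats::complete.cases(bundle$scores)
  vcols <- grep("^V[0-9]+$", names(bundle$scores), value = TRUE)
  if (sum(sel) > length(vcols) + 1 && length(unique(moa[sel])) == 2L) {
    bundle$manova <- run_stage("manova", manova_oneway(
      as.matrix(bundle$scores[sel, vcols]), moa[sel]))
  }

  if (length(unique(moa[sel])) == 2L) {
    chem2 <- bundle$scores$chemical_id[sel]
    sub <- subset_panel(panel, panel$info$chemical_id %in% chem2 |
                          panel$info$binned_level == "none")
    basis <- make_bspline_basis(c(0, max(panel$grid)), config$n_basis,
                                config$degree, grid = panel$grid)
    design <- run_stage("bspline-design", build_design(sub, basis, with_groups = TRUE))
    bundle$bspline <- run_stage("bspline-fit", fit_lmm(design))
    bundle$contrasts <- run_stage("contrasts", group_contrasts(bundle$bspline,
                                                               q = config$q))
    bundle$kmeans <- run_stage("kmeans", kmeans_cluster(
      as.matrix(bundle$scores[sel, vcols]), k = 2L,
      seed = derive_seed(config$seed, "kmeans"),
      n_start = config$kmeans_restarts, truth = moa[sel]))
    bundle$som <- run_stage("som", som_cluster(
      as.matrix(bundle$scores[sel, vcols]), spec = config$som,
      seed = derive_seed(config$seed, "som"), truth = moa[sel]))
  }

  if (!is.null(out_dir)) {
    run_stage("write", {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_table(bundle$scores, file.path(out_dir, "scores.csv"))
      if (!is.null(bundle$contrasts)) {
        write_table(bundle$contrasts, file.path(out_dir, "contrasts.csv"))
      }
      if (!is.null(bundle$manova)) {
        write_table(bundle$manova, file.path(out_dir, "manova.csv"))
      }
      if (!is.null(bundle$binning)) {
        write_table(as.data.frame(bundle$binning$ari_matrix),
                    file.path(out_dir, "ari_matrix.csv"))
      }
    })
  }
  bundle
}
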