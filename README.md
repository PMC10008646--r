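# tcrcfda

Functional mixed-effects modelling and unsupervised clustering of
**time-dependent cellular response curves** (TCRCs) from impedance-based
cytotoxicity assays.

## The problem

Real-time cell analysers record, for every well of a plate, how the **Cell
Index** (CI) — an impedance-derived proxy for cell number, morphology and
adhesion — evolves after a chemical is added. A typical experiment screens
dozens of chemicals at an 11-point 1:3 dilution series, yielding hundreds of
curves observed hourly over 72 h. The scientific question is whether the
*shape* of these curves identifies a chemical's **mode of action** (MOA) —
how it attacks the cells — without supervision, so that future cytotoxicity
screens can be triaged automatically.

`tcrcfda` provides the full analysis chain for this problem:

1. **Preprocessing** — CI from frequency-dependent impedance
   (`CI = max_i(R_cell(f_i)/R_b(f_i) - 1)`), normalization to the Normalized
   Cell Index (`NCI[k] = CI[k]/CI[0]`, anchoring every curve at 1 at
   treatment time), and cubic-spline interpolation onto a common hourly grid.
2. **Concentration binning** — concentration levels that produce essentially
   the same curves are merged, data-drivenly: per-concentration functional
   k-means on level-4 DWT scaling coefficients, pairwise Adjusted Rand
   Indices between the 11 labelings, complete-linkage clustering on `1 - ARI`,
   cut at three bins (*high*, *medium*, *low*). Curves from different
   concentrations in one bin are then treated as replicates.
3. **The functional linear mixed model.** Each curve is modelled as

   ```
   Y_tco(t) = mu_t(t) + B_tc(t) + E_co(t) + eps_tco(t)
   ```

   with fixed concentration-level means `mu_t`, a concentration-specific
   functional random intercept `B_tc` per chemical `c`, a smooth error
   process `E_co` per curve, and white measurement noise. The model is fitted
   two ways:
   * **fPCA route** — moment-based separation of the `B` and `E` covariance
     surfaces, quadrature-weighted eigendecomposition (Karhunen–Loève), and
     BLUP prediction of the per-chemical scores `V1..V3` (high), `V4..V6`
     (medium), `V7..V9` (low);
   * **B-spline route** — projection onto 4 cubic B-splines on [0, 72] h and
     a multivariate linear mixed model (REML, unstructured 4×4 covariance
     blocks per level for chemicals, one per-curve block, scalar noise), with
     MOA-group contrasts tested under Benjamini–Yekutieli FDR control
     (BY rather than BH because the contrasts are mutually dependent).
4. **Clustering and testing** — k-means (restarted) and an online Kohonen
   self-organizing map (bubble/gaussian kernel, rectangular/hexagonal
   topology, planar/toroidal structure) on any projected feature set;
   permutation-matched accuracy, confusion matrices, ARI and BSS/TSS;
   one-way MANOVA (Wilks, Pillai, Hotelling–Lawley, Roy) on score vectors.

Because the assay data this methodology was developed on are
access-restricted, the package ships a **synthetic-data module**
(`simulation_design()`, `make_truth()`, `simulate_panel()`) that generates
panels with exactly the statistical structure the models assume — 63
chemicals × 11 concentrations + 12 controls = 705 curves by default, with
known ground-truth scores for parameter-recovery testing.

## Worked example

```r
library(tcrcfda)

design <- simulation_design()              # 63 chemicals, 11 conc., 12 controls
truth  <- make_truth(design)               # generative ground truth
panel  <- simulate_panel(truth, design, seed = 1)
panel
#> curve_panel: 705 curves x 72 time points [1, 72] h (nci scale)
#>   chemicals: 63 | controls: 12 | binned levels present: 4

fit <- fit_fpca(panel, n_fpc = 3)          # FLMM via functional PCA
fit
#> fpc_model:
#>   high    lambda = 11.36, 1.943, 0.2837
#>   medium  lambda = 5.381, 1.266, 0.1348
#>   low     lambda = 1.999, 0.5078, 0.07888
#>   E block: 15 component(s) | sigma2 = 0.009924

scores <- predict_scores(panel, fit)       # BLUP scores V1..V9 per chemical
head(scores[, 1:6], 3)
#>   chemical_id moa_label   V1     V2      V3      V4
#> 1     chem001    group1 1.44 -0.456 -0.4911  4.7633
#> 2     chem002    group1 3.28 -0.237  0.0194 -0.0183
#> 3     chem003    group1 3.84  0.834  1.1696  2.4427

two <- scores$moa_label %in% c("group1", "group10")
manova_oneway(as.matrix(scores[two, paste0("V", 1:9)]), scores$moa_label[two])
#> One-way MANOVA (exact p-values)
#>         statistic  value approx_f df1 df2        p
#>             Wilks 0.1006    22.84   9  23 1.99e-09
#>            Pillai 0.8994    22.84   9  23 1.99e-09
#>  Hotelling-Lawley 8.9364    22.84   9  23 1.99e-09
#>               Roy 8.9364    22.84   9  23 1.99e-09

kmeans_cluster(as.matrix(scores[two, paste0("V", 1:9)]), k = 2, seed = 2,
               truth = scores$moa_label[two])
#> cluster_report: 33 observations, 2 clusters, BSS/TSS = 0.456
#>   accuracy vs truth: 93.94% | ARI: 0.765
```

The eigenvalue ladders show how chemical-induced variability concentrates in
the first component of each concentration level and shrinks from *high* to
*low* dose; the MANOVA rejects equality of the two MOA groups' score means
(the four statistics share one exact F because there are two groups); the
k-means report gives the permutation-matched accuracy against the true group
labels. `run_pipeline(pipeline_config(seed = 1), panel)` chains binning,
both model fits, MANOVA, contrasts and clustering in one call and writes all
result tables as CSV.

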