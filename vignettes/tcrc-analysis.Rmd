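---
title: "Functional mixed-effects analysis of cellular response curves: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional mixed-effects analysis of cellular response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrcfda)
```

# The data and the model

A time-dependent cellular response curve (TCRC) records the Normalized Cell
Index of one well over the 72 hours following chemical treatment, on a
common hourly grid `t = 1..72`. The pre-treatment anchor point (where the
NCI is 1 by construction) is consumed by the normalization and not stored;
stored curves therefore start *near* one, exactly one only in the absence of
noise. An experiment contributes, per chemical, one curve at each of 11
concentrations of a 1:3 dilution ladder, plus untreated control curves.

After the concentration ladder is reduced to three binned levels
(section below), every curve is modelled as

$$Y_{\tau co}(t) = \mu_\tau(t) + B_{\tau c}(t) + E_{co}(t) + \varepsilon_{\tau co}(t),$$

where $\tau$ indexes the binned level (high/medium/low), $c$ the chemical,
$o$ the replicate; $\mu_\tau$ is the fixed level mean, $B_{\tau c}$ a
*concentration-specific functional random intercept* for the chemical,
$E_{co}$ a smooth error process per curve, and $\varepsilon$ white
measurement noise with variance $\sigma^2$ at each grid point. $B$ and $E$
are zero-mean, mutually uncorrelated processes; the covariance of $B$ is
allowed to differ across levels because point-wise variation differs
strongly between doses. Curves from different concentrations within one bin
are treated as replicates of the binned dose — that is what binning buys:
enough replication to estimate the level-specific covariance of $B$.

One indexing ambiguity had to be resolved: whether the smooth error is
shared across a chemical's concentrations or attached to each observed
curve. We treat each observed curve as carrying its own smooth error (the
per-curve reading of $E_{co}$); the shared alternative would induce
cross-level correlation that the moment estimators below deliberately do not
model.

# Concentration binning

Each curve is summarized by the approximation (scaling) coefficients of a
level-4 discrete wavelet transform. No wavelet family or boundary rule is
canonical for this assay, so both are configuration: the default is
Daubechies-4 (`db4`, 8 taps) with periodized extension, the choice that
keeps coefficient counts minimal and maps a constant signal to exactly zero
detail coefficients. The transform is implemented in the package as a
periodized filter cascade; odd intermediate lengths (72 halves to 9 after
three levels) are extended by repeating the last sample, the standard
treatment for non-dyadic lengths, giving 5 coefficients for a 72-point curve
at level 4 and 50 for the 792-point concatenation of a chemical's 11 curves.
Numeric coefficient values are deliberately not an acceptance surface; the
tests pin structural identities (filter orthogonality, energy preservation
on dyadic lengths, the constant-signal identity, coefficient counts).

For each concentration index, chemicals are split into two groups by
k-means on these coefficients (Euclidean distance on scaling coefficients
approximates the $L^2$ distance on curves for orthonormal wavelets; 100
restarts, best within-cluster sum of squares, fixed seed). The 11 resulting
binary labelings are compared pairwise by the Adjusted Rand Index, and
complete-linkage hierarchical clustering on $1-\text{ARI}$, cut at three
clusters, groups concentrations that partition the chemicals the same way.
Bins are named by mean concentration index — the bin holding the lowest
indices (strongest doses) is *high*. Two degenerate cases are pinned by
convention: when both labelings in an ARI comparison are single-cluster the
pair-counting formula is 0/0 and we define ARI = 1 for identical partitions
and 0 otherwise; when all 11 labelings coincide the ARI matrix is all ones,
any cut is valid, and the binning falls back to a contiguous index split.

# The fPCA route

Estimation is by method of moments on residuals $r = Y - \hat\mu_\tau$, with
$\hat\mu_\tau$ the pointwise level average (optionally spline-smoothed;
default raw, because averaging hundreds of curves on a dense hourly grid is
already smooth):

* **Chemical covariance** $K_{B,\tau}(s,t)$: average of cross-products
  $r_o(s) r_{o'}(t)$ over ordered replicate pairs $o \neq o'$ within each
  (level, chemical) cell, symmetrized. Replicates share $B_{\tau c}$ but
  have independent smooth errors, so cross-products are unbiased for
  $K_{B,\tau}$. If no cell anywhere has two replicates, $B$ and $E$ are not
  separable and the fit aborts with an identifiability error.
* **Smooth-error covariance** $K_E$: average over curves of
  $r r^{\top} - K_{B,\tau(\text{curve})}$. Its off-diagonal is unbiased for
  $K_E$; the diagonal is contaminated by $\sigma^2$ and is replaced by
  linear extrapolation along the ridge from the first two off-diagonals
  ($2 v_1 - v_2$ at each grid point). On a dense 1-hour grid this local rule
  suffices and no bivariate smoothing of the raw surfaces is performed;
  smoothing remains available through the mean-penalty switch.
* **Noise variance**: the mean remaining diagonal deficit, truncated at
  zero.

Control curves carry no chemical: they enter $\hat\mu_{none}$, $K_E$ and
$\sigma^2$ only, and no $B$ block exists for the *none* level.

Eigendecomposition is quadrature-weighted: with trapezoid weights $W$ the
symmetric matrix $W^{1/2} K W^{1/2}$ is decomposed, negative eigenvalues are
dropped (a positive-semidefinite projection — moment estimates of covariance
surfaces are not PSD in finite samples), and eigenfunctions
$\phi = W^{-1/2}v$ come back orthonormal under the trapezoid inner product.
Scores are sign-ambiguous, so a gauge is fixed: the sign making
$\int \phi \ge 0$, falling back to a positive leading non-negligible value
when the integral is essentially zero. Three components per $B$ block are
retained by default — the first three functional principal components carry
almost all chemical-induced variability — while the $E$ block keeps enough
components for 95% of its positive spectrum.

Score prediction is the posterior mean under the working Gaussian model.
Because replicates within a (level, chemical) cell share the chemical
effect, the BLUP depends on the cell's average residual $\bar r$:

$$\hat b = \Lambda \Phi^{\top}\left(\Phi \Lambda \Phi^{\top} +
  \tfrac{1}{n_o}(\Phi_E \Lambda_E \Phi_E^{\top} + \sigma^2 I)\right)^{-1} \bar r,$$

a formula with two limiting behaviours the tests pin down: as
$\sigma^2 \to 0$ with data in the span of an eigenfunction it reduces to the
quadrature inner product $\int \bar r\,\phi$, and for a single noisy curve
each component is the least-squares projection shrunk by
$\lambda/(\lambda + \sigma^2)$. Scores are laid out V1..V3 (high), V4..V6
(medium), V7..V9 (low). A chemical missing a level gets `NA` scores —
flagged, never imputed.

# The B-spline route

The local-time analysis projects the same mixed model onto cubic B-splines.
The basis deserves a note: describing the design as splitting [0, 72] into
four intervals while using exactly four cubic B-splines is internally
inconsistent — a cubic spline space over four intervals has dimension 7.
The package resolves this with the standard rule
`n_interior = n_basis - degree - 1 = 0`: four cubic B-splines on a single
interval, i.e. the cubic Bernstein-type basis, which satisfies partition of
unity and endpoint interpolation. The 7-function interior-knot alternative
is available by setting `n_basis = 7`.

Per chemical the curves are stacked over (time, replicate, level) and
centred by the pointwise grand mean over all treated curves — handling the
global mean $\mu(t)$ as pre-centering rather than 72 free parameters keeps
the fixed-effect matrix full-rank. Fixed effects are (level × spline)
coefficients, crossed with the MOA group when group contrasts are wanted;
random effects are an unstructured 4×4 block per level for each chemical
and one unstructured 4×4 block per curve, mutually independent, plus scalar
noise. REML estimation is delegated to `lme4::lmer` (the canonical REML
implementation in R); positive-semidefiniteness of the blocks is guaranteed
by lme4's Cholesky parameterization and the fit is deterministic given
starting values, which the interface exposes for warm-started simulation
studies.

Group contrasts $\beta_{\tau,10,i} - \beta_{\tau,1,i}$ are Wald tests with
the standard error from the fixed-effect covariance and residual degrees of
freedom $n - \operatorname{rank}X$ (Satterthwaite/Kenward–Roger corrections
are out of scope; at $n$ in the tens of thousands the df choice is
immaterial). The twelve p-values are adjusted by Benjamini–Yekutieli, which
divides the BH thresholds by $c(m)=\sum_{j=1}^m 1/j$ and is valid under the
arbitrary dependence these contrasts exhibit; it is uniformly more
conservative than BH, which the tests verify as a subset relation on
rejections. The package reports however many contrasts pass at the chosen
FDR level; no count is assumed.

Curve prediction omits the replicate effects:
$\hat\mu + \Phi(\hat\beta_\tau + \hat u_{\tau c})$.

# Clustering and MANOVA

k-means uses restarted Lloyd iterations; reports carry BSS/TSS (which the
tests check conserves BSS + WSS = TSS exactly), and — when reference labels
exist — the confusion matrix, ARI, and permutation-matched accuracy
(brute-force maximization over label matchings, up to six classes; the
matching rule matters, since cluster labels are arbitrary).

The self-organizing map is an online Kohonen network implemented in the
package, exposing exactly the four choices known to matter: neighbourhood
kernel (gaussian/bubble), topology (rectangular/hexagonal, the latter with
axial offset distances), structure (planar/toroidal, the latter wrapping
grid distances), and grid size. Schedules are linear — learning rate 0.05 to
0.01, radius from half the grid diameter to zero over 50 epochs — and node
initialization samples data rows under the stage seed. With radius zero and
the bubble kernel the update rule is exactly online k-means, which anchors
the implementation against `stats::kmeans` in the tests. `som_sweep()`
iterates the full factorial of these settings.

One-way MANOVA on score vectors reports Wilks, Pillai, Hotelling–Lawley and
Roy with their standard approximate-F transformations, via `stats::manova`
plus identifiability checks (a singular within-group scatter aborts naming
the offending columns). With two groups the four statistics share a single
exact F — the output flags this — so a two-group score table yields one
p-value four ways, and the null distribution of that p-value is uniform,
which the test suite verifies by simulation.

# The synthetic-data generator

The generator is the package's stand-in for restricted assay data and
defines the conditions under which every recovery property is tested. Its
defaults emulate the study layout: 63 chemicals in three MOA groups
(20 + 13 + 30), 11 concentrations binned {1–4}/{5–8}/{9–11}, 12 controls,
hourly grid over 72 h — 705 curves.

* **Means** are four-phase growth curves (lag, log, plateau, decline)
  anchored at 1: controls and low doses rise to a plateau with mild decline,
  medium doses rise then fall below baseline, high doses decline toward
  zero.
* **Eigenfunctions** are orthonormalized half-period sines for the chemical
  effect and quarter-period sines for the smooth error; all vanish at the
  first grid point so simulated NCI curves start at 1 up to white noise.
* **Variances** default to $\lambda_B = (4, 1, 0.25)$ scaled by
  (1, 0.6, 0.3) across high/medium/low — dose-dependent chemical variability
  with a dominant first component, matching what the fitted eigenvalue
  ladders look like on real-data analyses of this assay class —
  $\lambda_E = (0.5, 0.1)$, and $\sigma^2 = 0.01$, which together produce
  visually TCRC-like curves on the NCI scale.
* **Group separation** is a pure mean shift in score space: group score
  means sit `margin * sqrt(lambda)` apart along directions spread on the
  unit circle in the first two components (default margin 1.5, covariances
  equal across groups — the simplest structure consistent with testing mean
  differences). The magnitude of real-data group separation is unknown;
  the margin is a free parameter, not an estimate.
* **Unbinned mode** gives every concentration index its own mean — the bin
  mean plus a small within-bin dose perturbation (default 0.1 times a
  smooth bump, graded by position within the bin) — and withholds the bin
  labels, so the binning stage has a planted partition to discover; the
  shared chemical effect within each true bin is what makes per-index
  labelings agree within bins.

Known limitations of the generator, hence of what passing tests show about
real data: group-separation directions are identical across bins, which
makes per-concentration labelings agree *across* bins through the group
split and erodes the within-bin/between-bin ARI contrast — with the full
63-chemical default panel the planted partition is recovered in 19 of 20
seeds, but on a 33-chemical two-group subset recovery drops to roughly 70%;
dose–response within a bin is absorbed into smooth error rather than
modelled; group heterogeneity inside the remainder group is ignored; and
curves are generated directly on the NCI scale, so the impedance-to-CI and
interpolation steps are exercised only by their own unit tests.

# Numerical choices and test problem sizes

Trapezoid quadrature everywhere a functional inner product is needed; PSD
projection by truncating negative eigenvalues; the eigenfunction sign gauge
and degenerate-ARI conventions above; interpolation never extrapolates
(curves not covering the grid are rejected — fabricated late-time behaviour
would feed the models' most informative region); the smoothing penalty for
irregular raw series defaults to exact interpolation, with generalized
cross-validation available, since the accuracy of the original
interpolation procedure is documented but its penalty is not.

Simulation-based properties run at sizes chosen to make the checks sharp
but affordable: parameter recovery at 1,000 chemicals (eigenvalues and noise
within 20%, eigenfunction alignment above 0.95), sampler checks at 10,000
score draws (variance within 5%) and 2,000 chemicals (covariance surface
within 10% Frobenius), MANOVA null uniformity over 2,000 replicates, and
the Benjamini–Yekutieli power property over 200 replicates of a reduced
single-level design (10 chemicals, 24-point grid, three replicates,
warm-started REML refits) where a planted five-standard-error contrast must
be detected at least 90% of the time. Master seeds feed every stage through
a fixed stage-name hash, so partial re-runs reproduce full-pipeline results
bit for bit.
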