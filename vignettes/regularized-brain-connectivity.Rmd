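---
title: "Voxel-level regularized brain connectivity: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-level regularized brain connectivity: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbconn)
```

## The estimation problem

Resting-state functional connectivity is usually summarised per voxel
either by seed correlations or by averages of bivariate correlations
(weighted global brain connectivity, GBC).  Averages are robust but blind
to *how* coupling is organised: a voxel correlated 0.6 with five partners
and a voxel correlated 0.3 with ten partners can have the same average
while being very differently embedded in the network.  `rbconn`'s core
estimator treats connectivity as a prediction problem: regularized brain
connectivity (RBC) is the correlation between a voxel's observed series
and the series predicted from *all* other gray-matter voxels by ridge
regression,

$$\mathrm{RBC}_i \;=\; \mathrm{Cor}\!\left(\hat Y_i,\; Y_i\right),
\qquad
\hat\beta \;=\; \arg\min_\beta \;\|Y_i - X_{-i}\beta\|^2 + \lambda\|\beta\|^2 ,$$

with $X_{-i}$ the $N \times (p-1)$ matrix of the remaining standardized
voxel series.  This is the multiple correlation of a penalized fit; it
equals the square root of the model's coefficient of determination in the
unpenalized limit.

### Why the dual (Gram) form

With $p$ in the tens of thousands and $N$ a few hundred, the primal
normal equations are intractable, but the ridge fit depends on the data
only through the $N \times N$ Gram matrix $K = YY^\top$:
$\hat Y_i = K_{-i}(K_{-i} + \lambda I)^{-1} Y_i$ with
$K_{-i} = K - Y_iY_i^\top$.  `rbconn` factorizes $K + \lambda I$ once per
subject (Cholesky) and obtains each leave-one-voxel-out solution through
the Sherman–Morrison identity
$\alpha_i = z_i / (1 - Y_i^\top z_i)$, $z_i = (K+\lambda I)^{-1}Y_i$,
which is algebraically exact (the denominator is strictly positive because
$K \succeq Y_iY_i^\top$).  Tests verify this against the explicit rank-one
downdate, an independent primal solver, and `glmnet`.

Because the smoother $K_{-i}(K_{-i}+\lambda I)^{-1}$ is symmetric positive
semi-definite, $\mathrm{Cov}(\hat Y_i, Y_i) = Y_i^\top S Y_i \ge 0$: RBC is
intrinsically nonnegative, and the package asserts this on every map.

### The penalty λ

* **Scale.**  λ is on the raw scale `RSS + λΣβ²`.  Packaged ridge solvers
  often rescale internally; for `glmnet`, `lambda ≈ λ/N` (exactly
  `λ·sd₁/N(y)/N`), which the test suite uses for the cross-check.
* **Fixed across voxels and subjects.**  RBC values are only comparable if
  every fit is shrunk identically, so λ is a single analysis-wide constant.
* **No cross-validation.**  BOLD series are temporally autocorrelated, so
  i.i.d. resampling schemes are biased; rather than pretend otherwise the
  package requires an explicit λ (or grid).  The conventional grid is
  (0.5, 1, 5, 10, 50, 100, 500) with 50 as the default single value.
* **Regimes.**  As λ → 0⁺ with p ≥ N the fit interpolates and RBC → 1 for
  every voxel (a tested contract, not a useful analysis point).  As
  λ → ∞ the fitted series tends to the direction $K_{-i}Y_i$ and RBC tends
  to $\mathrm{Cor}(K_{-i}Y_i, Y_i)$.  Informative shrinkage happens when λ
  is comparable to the bulk Gram eigenvalues, which for standardized data
  are of order p for unstructured noise; strongly correlated real data
  concentrate their spectrum and leave many small noise directions that
  moderate λ suppresses.

### Degenerate cases and numerical conventions

* Constant voxel series cannot be standardized; they are removed from the
  predictor set and reported as missing (`NA`) in every map, never
  propagated as NaN.
* A fitted series with standard deviation below 1e-14 is treated as
  degenerate and assigned RBC 0.  The threshold is far below any genuine
  fit but far above floating-point noise, so the λ → ∞ direction limit
  (fitted values of order 1/λ) is *not* misclassified as degenerate.
* Correlations are clipped at 1 − 1e-12 before the Fisher transform so
  that values numerically equal to 1 (tiny λ) map to a large finite
  number.
* All solvers are deterministic: Cholesky/backsolve and `svd`, no
  randomized algorithms, so identical inputs give bit-identical maps.

## Comparison estimators

**GBC** is the mean absolute Pearson correlation of a voxel with every
other in-mask voxel, computed exactly (`crossprod` of the standardized
matrix; an O(p²) loop oracle checks it in tests).

**NRC** (supervised principal-component regression) screens predictors by
marginal |correlation| with the target — either a threshold θ or a top
fraction q — extracts principal components of the screened block, and
regresses the target on the first m components by OLS.  The original
hyperparameters are not restated in the connectivity literature this
implements, so the package declares its own defaults, q = 0.05 and m = 3,
both configurable.  An empty screen yields 0 by convention; m is clipped
(with a warning) when fewer components exist.

## Preprocessing operations

The package consumes *preprocessed* BOLD (motion correction, denoising and
spatial normalization are upstream, out of scope) and provides only the
steps the estimators depend on:

* **Masking** to an N × p matrix in fixed raster order (x fastest, 0-based
  coordinates), so maps are aligned across subjects by construction.
  Only axis-aligned geometries are accepted; oblique affines are rejected.
* **Block-mean downsampling** (e.g. to a 4 mm grid) for cost reduction.
  Block means preserve per-volume signal means exactly on divisible grids;
  trailing partial blocks average the available voxels.  Masks are
  downsampled by majority vote (> 50% coverage).  An interpolating scheme
  was deliberately not used: the purpose is decimation, not resampling
  fidelity.
* **Band-pass filtering** (default 0.02–0.1 Hz) as a hard DFT mask with DC
  always removed.  A hard mask, unlike a Butterworth filter, is exactly
  idempotent and testable bin by bin; only the retained band is part of
  the scientific contract.
* **Standardization** to mean 0, variance 1 (divisor N − 1).

## Group inference

Per-voxel t statistics for the regressor of interest are computed after
residualizing both the maps and the regressor against the nuisance
covariates plus intercept (Frisch–Waugh, identical to the full-model
partial t; for a two-group design without nuisance this is exactly the
pooled two-sample t, the same formula used for summary-statistic cohort
tables).  Significance is assessed by permutation of the maximum TFCE
score:

* **TFCE** with the method's standard published defaults E = 0.5, H = 2,
  26-connectivity, and dh = max(stat)/100 recomputed per map (the behaviour
  of the reference implementation); the integration is implemented in C++
  with flood-fill component labelling and verified against closed-form
  summations, a Riemann-vs-analytic limit, and a monotonicity property.
* **Freedman–Lane** for nuisance covariates: residuals from the
  nuisance-only model are row-permuted and the nuisance fit added back.
  Whether the original analyses permuted labels directly or used a
  design-matrix scheme is not documented; Freedman–Lane is this package's
  declared choice, being the default of the tool of record for this kind
  of analysis.
* **p-values** follow (b + 1)/(m + 1), never smaller than 1/(m + 1).  When
  the number of distinct permutations (label reassignments for a simple
  two-group design, row permutations otherwise) does not exceed the
  requested count, the null is enumerated exactly and the result is
  seed-independent; fewer than 20 distinct permutations triggers a
  resolution warning.
* **Two-sided inference** runs two one-sided enhancements (positive and
  negative) with a Bonferroni factor of 2, mirroring how increases and
  decreases are reported separately in group studies.
* Voxels missing in any subject are excluded from inference.

## The synthetic cohort generator

Each in-mask voxel's series is a weighted sum of latent signals shared
within voxel communities plus stationary AR(1) noise:
$y_v(t) = \sum_c w_{vc}\, L_c(t) + \varepsilon_v(t)$.  Latents are
unit-variance band-limited Gaussian processes (equal power on every
Fourier bin inside 0.02–0.1 Hz, random phases), matching the default
acquisition regime the package emulates: 256 volumes at TR = 2 s on a
coarse 4 mm-like grid.  AR(1) noise (default ρ = 0.3, σ = 1) is used
instead of white noise precisely because temporal dependence is the reason
cross-validation is excluded from the λ contract; the stationary noise
variance is σ²/(1 − ρ²).

Closed forms used as test oracles: marginal variance
$\sum_c w_{vc}^2 + \sigma^2/(1-\rho^2)$ and pairwise correlation
$w_i w_j / \sqrt{(w_i^2+\sigma'^2)(w_j^2+\sigma'^2)}$ for voxels sharing
one latent.

Group effects are multiplicative factors on patients' coupling weights;
setting every factor to 1 makes the two groups' laws identical, giving the
exactly exchangeable null used for type-I calibration.  Community
memberships may additionally be restricted to one group: a purely
multiplicative factor cannot *create* a coupling that controls lack, and
the reallocation scenario below needs exactly that.

### What the generator does not emulate

No hemodynamic response convolution, no motion or scanner artifacts, no
spatial autocorrelation of the noise, no global signal.  Passing tests
therefore demonstrate the estimators' statistical behaviour under a
controlled latent-network model, not performance on real fMRI; in
particular real data's smoothness concentrates the Gram spectrum in ways
the white-noise background here does not.

### The "multivariate-only" effect scenario

`multivariate_effect_spec()` plants a group difference designed to be
invisible to a bivariate average but visible to a multivariate estimator.
A contiguous 12-voxel block splits, for controls, into two interleaved
6-voxel cliques with strong in-clique coupling $w_1 = 1.4$ (in-clique
correlation $c_1 = w_1^2/(w_1^2+\sigma'^2) \approx 0.64$).  For patients
the coupling is reallocated onto a single merged latent with weaker
coupling $w_2$, plus a per-voxel private latent topping the marginal
variance up to the control value.  $w_2$ is set by solving

$$11\, \mathrm{E}|r(c_2)| \;=\; 5\, \mathrm{E}|r(c_1)| + 6\, \mathrm{E}|r(0)|$$

at the cohort's number of time points ($\mathrm{E}|r(\cdot)|$ via the
Fisher-z normal approximation), so each block voxel's *expected mean
absolute sample correlation* — exactly the quantity GBC averages — is
unchanged, sampling-noise floor included.  Multiple R², being convex in
the individual correlations, drops substantially for patients
(concentrated strong predictors beat the same average spread thinly), so
the block carries a genuine RBC reduction.  Two deliberate design points:

* An earlier, simpler idea — matching *every pairwise correlation* across
  groups — is impossible to combine with an RBC effect: both GBC and the
  multiple correlation are functions of the correlation matrix alone, so
  exact pairwise matching nulls every second-order estimator.  Matching
  only the per-voxel *mean* |r| is the strongest GBC-invariance compatible
  with a multivariate effect.
* The mask is kept small (40 voxels) so that the conventional fixed
  penalty λ = 50 is comparable to the noise-bulk Gram eigenvalues (order
  p) and therefore shrinks informatively; on a much larger unstructured
  mask the same λ would barely regularize and in-sample RBC would saturate
  toward 1 for all voxels, erasing any contrast.

## Problem sizes used by the shipped checks

The calibration and power studies are run at desk scale, chosen so the
full suite completes in minutes while keeping each test statistically
meaningful: type-I calibration uses 200 independent null cohorts (10
subjects/group, 210 voxels, 128 time points, 200 permutations) and checks
the family-wise false-positive rate against the binomial 95% band around
0.05; the power-ordering study uses 50 planted-effect cohorts (10
subjects/group, 40 voxels, 96 time points, 100 permutations) and requires
RBC at λ = 50 to flag at least as many FWE-significant voxels as GBC in at
least 80% of repetitions.  Generator-fidelity checks use a single 4096
time-point series so Monte-Carlo error (≈ 0.016 for a correlation) sits
well inside the ±0.05 acceptance band.

## Known limitations

* Only axis-aligned NIfTI geometries; oblique acquisitions must be
  resampled upstream.
* NRC recomputes an SVD per target voxel; it is the slowest estimator and
  intended for moderate masks (the analyses it is compared in use the
  same 4 mm-grid scale).
* The permutation engine enumerates exhaustively only for simple two-group
  designs or very small n; otherwise it samples with replacement from the
  permutation group, the standard Monte-Carlo practice.
* Negative associations between fitted and observed series are impossible
  for RBC/NRC by construction; the two-sided machinery exists for group
  contrasts on the transformed maps, not for the maps themselves.
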