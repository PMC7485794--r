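---
title: "Canopy chlorophyll inversion: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy chlorophyll inversion: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlospec)
```

## The problem

Chlorophyll content (mg/L of pigment extract) is the standard proxy for the
nitrogen and growth status of japonica rice. Field campaigns measure it
destructively: leaves are extracted in acetone/ethanol and the optical
densities of the extract at 663 and 645 nm are converted by the two-band
formula

$$Chl = 5.134\,OD_{663} + 20.436\,OD_{645},$$

implemented in `chl_from_od()`. An airborne push-broom imager, by contrast,
sees only canopy reflectance between 400 and 1000 nm. **chlospec**
implements the full inverse-modeling chain that connects the two: radiometric
calibration, spectral preprocessing, band selection, and a nonlinear
regression from a handful of characteristic wavelengths to chlorophyll.

## Radiometry and the wavelength grid

Raw sensor digital numbers (DN) are converted to reflectance by two-point
black-white correction against dark and white reference panels of known
reflectivity,

$$\rho_t = \frac{DN_t - DN_1}{DN_2 - DN_1}\,(\rho_2 - \rho_1) + \rho_1.$$

The map is affine and strictly monotone whenever the panel DNs differ; the
degenerate case is rejected at construction (`calibration_pair()`).

The band grid is normative for the package: `make_grid(start, end, step)`
produces `floor((end - start)/step)` bands with band *k* (0-based) centred
at `start + (k + 0.5) * step`. The 400--1000 nm range at the imager's
2.35 nm resampling interval gives 255 bands; removing one resampling-artefact
band per boundary leaves 253 effective bands; chlorophyll analysis then
restricts to 400--800 nm, where pigment absorption and the red edge live
(the NIR plateau beyond 800 nm carries structural, not pigment,
information). Only the band *counts* are published for the source
instrument; the half-step-offset center convention is this package's own
fixed choice, and every wavelength-indexed result depends on it.

## Preprocessing

`savgol_smooth()` applies Savitzky--Golay convolution smoothing per
spectrum. Interior bands use the centred least-squares filter; at the
boundaries the window truncates one-sided and the polynomial degree drops to
at most (window size − 1), so the filter stays exact on polynomials up to
the configured degree everywhere. Defaults are window 11 (≈26 nm) and
degree 3 — conventional for reflectance sampled at ~2.35 nm, and
configurable. The filter is linear and preserves constants exactly.

Per-band signal quality is summarised as
$SNR_{dB} = 10\log_{10}(\overline{x^2}/\mathrm{var}(x))$ across samples,
with the population variance. The phrase "power over variance" admits a
per-band or a pooled reading; the package computes per band and attaches a
pooled summary as an attribute, so both are available.

## Synthetic study conditions

No field dataset is distributed, so the package carries its own forward
model (`synthetic_config()` / `generate_dataset()`), and every downstream
claim is tested against it. The generator emulates:

* **Chlorophyll distribution.** Truncated normal via rejection sampling,
  defaults mean 54.66, SD 26.94, range 2.60--99.70 mg/L, n = 196 — the
  summary statistics of the motivating field campaign, whose coefficient of
  variation exceeds 40% (high dispersion across growth stages).
* **Curve shape.** A low visible shelf (0.05) rising through a logistic red
  edge (width 16 nm) to a NIR plateau (0.45).
* **Chlorophyll signal.** Gaussian absorption dips at 430 and 670 nm
  (widths 40/28 nm) whose depths grow linearly at 4×10⁻⁴ reflectance units
  per mg/L, and a red-edge inflection at 700 nm shifting +0.08 nm per mg/L —
  the two mechanisms by which real canopies encode pigment content. Dip
  gains are capped so the deepest dip stays above zero reflectance;
  saturating the clip floor would destroy the linear signal.
* **Noise.** 1% multiplicative then 0.002 additive Gaussian noise, then
  clipping to [0, 1].

What it deliberately does **not** emulate: radiative transfer
(PROSPECT/SAIL), canopy geometry and BRDF, atmospheric path radiance, soil
and water background, or inter-band noise correlation. Passing recovery
tests therefore demonstrates that the pipeline's machinery is correct and
self-consistent, not that field accuracy of any particular level is
attainable; the published field figures (R² ≈ 0.79, RMSE ≈ 8.2 mg/L)
cannot be reproduced without the original, undeposited campaign data.

`simulate_dn_scene()` closes the loop for calibration testing: it maps
reflectance to DN with a gain/offset plus sensor noise and emits the
matching panel pair, so `calibrate_reflectance()` round-trips exactly at
zero noise.

## Screening

`screen_bands()` ranks single bands by three association measures: Pearson
correlation (linear), distance correlation (the classical biased V-statistic
from doubly centred distance matrices — simple, and confined to [0, 1]), and
the maximal information coefficient. MIC is implemented as a bounded-grid
approximation: for each grid shape $r \times c$ with
$rc \le \max(4, \lfloor n^{0.6}\rfloor)$, one axis is equal-frequency
binned and the other axis's cut points are optimised exactly by dynamic
programming (minimising $\sum_b n_b H_b$, which is additive over segments);
mutual information is normalised by $\log_2 \min(r, c)$ and maximised over
shapes and both orientations. The DP kernel is C++ (`src/mic.cpp`); the
floor of 4 cells keeps the 2×2 grid admissible at small n. This is an
approximation of the full MIC search — published MIC values from other
estimators are comparable only qualitatively. Constant bands report
association 0 with a warning rather than an error, so a dead band cannot
abort a pipeline run.

## Band selection: SPA + MLR refinement

The successive projections algorithm (`spa_select()`) performs forward
selection that minimises collinearity: start from the column of largest
ℓ₂ norm, then repeatedly project all unselected (already residualised)
columns onto the orthogonal complement of the last selected vector and take
the largest residual. Residual norms are non-increasing by construction;
selection stops early, with a warning, when all residuals fall below the
1e−12 floor (noise-free spectra have low numerical rank, so this is a real
code path, not a corner case). The calibration matrix is the smoothed
*modeling-set* reflectance restricted to 400--800 nm — which is why the
data split runs before SPA in the pipeline, although selection itself never
sees the chlorophyll values.

`mlr_refine()` then scores every nonempty subset of the candidates (≤ 15,
so ≤ 32767 OLS fits) by **cross-validated** RMSE (5-fold, seeded). Training
RMSE would be monotone in subset size and always pick the full candidate
set; cross-validation is what makes "smallest RMSE" a meaningful selector
of a compact subset. Ties within 1e−10 relative resolve to the smaller,
then lexicographically earlier subset; fold-singular designs score +Inf.

A structural caveat the test suite makes explicit: with noise-free
synthetic data, the two absorption dips are almost exactly collinear (both
depths are linear in chlorophyll), so an anti-collinearity selector keeps
only one of them. The refined set lands on the red edge and one absorption
center — exactly what the method is designed to do, and a reminder that
"the physically planted bands" and "a minimal predictive subset" are
different sets.

## Inversion: ELM and PSO-ELM

`elm_fit()` is a single-hidden-layer network whose input weights and biases
are drawn uniformly on [−1, 1] and never trained; the output weights are
the Moore--Penrose solution `pinv(H) y` (via SVD), which both minimises the
residual and, among minimisers, the weight norm. With at least as many
hidden nodes as samples the network interpolates.

`pso_elm_fit()` wraps the random part in a global-best particle swarm: a
particle encodes the full input layer (weights column-major, then biases),
and its fitness is the *validation* RMSE of the ELM it decodes, with output
weights still solved analytically on the training set. Fitting to training
RMSE would reward interpolation and negate the search, so validation
fitness is the default (configurable). Velocity updates use
`v ← w·v + c1·r1·(pbest − x) + c2·r2·(gbest − x)` clamped to half the bound
width, and positions move as `x ← x + m·v` clipped to [−1, 1]. The
coefficient `m` scales the position update — the only reading consistent
with its published value range (0.02--1); a two-element `w` is a linear
inertia schedule with exact endpoints (`0.9~0.3` notation). The swarm
topology is global-best; the hidden-node count defaults to 20, with
`sweep_hidden_count()` provided because no automatic mechanism is published.

## Orthogonal-array tuning

`build_l25_design()` constructs the L25(5⁵) array from the canonical GF(5)
generator (run `5a + b + 1` gets levels `a, b, a+b, 2a+b, 3a+b` mod 5) —
verified in the tests to reproduce, row by row, the published 25-run
assignment bundled as `reference_orthogonal_runs()`. `marginal_analysis()`
computes `W[i, j]` = sum of run R² where factor *j* is at level *i*, and
selects per-factor argmax levels; `colSums(W)` is the same total for every
factor, a conservation identity the tests assert.

Two cells of the published analysis table disagree with recomputation from
its own run table: the inertia-weight column has its levels 4/5 sums
swapped, and the published choice "C2 = 2.8" conflicts with the C2 column's
actual maximum (3.838 at C2 = 1.65 vs 3.737 at 2.8). The package reports
the recomputed argmax; the pipeline's *default* swarm parameters
nevertheless keep the published working set (pop 50, w 0.9~0.3, C1 1.65,
C2 2.8, m 0.2) so that defaults match the documented reference
configuration.

## Evaluation and the pipeline

`r2_score()` is `1 − SS_res/SS_tot` (errors on constant truth), `rmse()`
the root mean square error in mg/L. Headline metrics are always computed on
the held-out validation set. The 84/16 modeling/validation split
(`split_dataset()`, 196 → 165/31) is stratified by chlorophyll quintile
with largest-remainder allocation, so both sets span the concentration
range and per-stratum counts deviate from proportionality by at most one.

`run_pipeline()` chains everything under one master seed, with each stage
drawing from a named substream (`derive_seed()`), so a rerun is
bit-identical and any stage can be reproduced in isolation. Unknown
configuration keys are rejected at construction.

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 11), out_dir = "run1")
res
#> == chlorophyll inversion pipeline ==
#> bands refined: 697.28, 798.32, 718.42, 403.52 nm
#> PSO-ELM  validation R^2 = 0.997, RMSE = 1.189 mg/L
#> ELM      validation R^2 = 0.996, RMSE = 1.339 mg/L
```

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale configurations
chosen once: 196-sample campaigns for recovery runs; swarms of 15--20
particles for 25--100 iterations; 20 paired seeds for the ELM vs PSO-ELM
median comparison; 50 seeded matrices (≤ 8×12) for the SPA oracle; 5-fold
CV throughout. Other fixed numerics: SPA residual floor 1e−12; subset-tie
tolerance 1e−10 relative; MIC cell bound `max(4, floor(n^0.6))`;
`which.max` ties resolve to the first (lowest) index everywhere; marginal
ties warn and take the lowest level.

## Known limitations

* The generator is phenomenological; none of the recovery numbers transfer
  to field data, and the published field metrics are out of reach by design.
* MIC is a bounded approximation (see above).
* The distance-correlation estimator is the biased V-statistic; it does not
  vanish exactly at independence for finite n.
* SPA on noise-free (rank-deficient) spectra returns fewer candidates than
  requested — by design, with a warning.
* Stratified splitting assumes the chlorophyll distribution is continuous;
  heavily tied values collapse strata and trigger the simple-split
  fallback.
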