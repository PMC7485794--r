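# chlospec

Inversion of rice canopy **chlorophyll content** (mg/L) from visible/NIR
hyperspectral reflectance, for remote-sensing and precision-agriculture
researchers who need the full chain from raw sensor counts to a validated
regression model — and a seeded synthetic test bed to exercise it without
field data.

The package implements, as composable stages:

* **Radiometric calibration** — black-white correction
  `ρ_t = (DN_t − DN_1)/(DN_2 − DN_1)·(ρ_2 − ρ_1) + ρ_1` against dark/white
  reference panels; wavelength-grid handling (400–1000 nm at 2.35 nm →
  255 bands → 253 effective → 400–800 nm analysis interval); a minimal
  ENVI cube reader (BSQ/BIL/BIP) with ROI-mean spectrum extraction.
* **Preprocessing** — Savitzky–Golay smoothing; per-band SNR
  `10·log10(power/variance)` in dB.
* **Screening** — per-band association with chlorophyll by Pearson
  correlation, distance correlation, and a grid-DP approximation of the
  maximal information coefficient (C++ kernel).
* **Band selection** — the successive projections algorithm (SPA):
  iterative orthogonal projection, keeping the largest-residual wavelength
  (`e_j = y_j − z(zᵀz)⁻¹zᵀy_j`), followed by exhaustive multiple-linear-
  regression subset refinement scored by cross-validated RMSE.
* **Inversion** — an extreme learning machine (random hidden layer, output
  weights `β = pinv(H)·y`), optionally with its input layer optimized by a
  global-best particle swarm (PSO-ELM) whose fitness is validation RMSE.
* **Tuning** — an L25(5⁵) orthogonal array over the swarm parameters
  (pop, w, C1, C2, m) with Taguchi-style marginal sums
  `W_ij = Σ R²(runs with factor j at level i)`, plus a bundled published
  reference experiment.
* **Ground truth** — chlorophyll from extract optical densities,
  `Chl = 5.134·OD663 + 20.436·OD645`; summary statistics; stratified 84/16
  modeling/validation splits.
* **Synthetic data** — a seeded forward model of canopy reflectance with
  chlorophyll-dependent absorption dips and red-edge shift, matched to the
  motivating field campaign's chlorophyll statistics (mean 54.66 mg/L,
  SD 26.94, range 2.6–99.7, n = 196).

## Worked example

```r
library(chlospec)

# wet-chemistry ground truth from extract absorbances
chl_from_od(0.62, 0.31)
#> [1] 9.51824            # mg/L

# end-to-end synthetic recovery run (196 samples, seeded)
res <- run_pipeline(pipeline_config(seed = 11))
res
#> == chlorophyll inversion pipeline ==
#> bands refined: 697.28, 798.32, 718.42, 403.52 nm
#> PSO-ELM  validation R^2 = 0.997, RMSE = 1.189 mg/L
#> ELM      validation R^2 = 0.996, RMSE = 1.339 mg/L
```

The pipeline generated a 196-sample canopy scene, simulated and calibrated
raw DNs, trimmed to 253 effective bands and 400–800 nm, smoothed, split
165/31 by chlorophyll quintile, selected characteristic bands with SPA
(here the red edge at ~697/718 nm, the NIR shoulder, and a blue
absorption-flank band), refined them by CV-RMSE, and fit PSO-ELM against
the plain-ELM baseline — both evaluated on the held-out 31 samples. RMSE is
in mg/L of chlorophyll; R² is the fraction of validation variance
explained.

Tuning the swarm instead of using defaults:

```r
mt <- marginal_analysis(build_l25_design(), reference_orthogonal_runs()$r2)
mt
#>          pop     w    c1    c2     m
#> level1 3.782 3.767 3.716 3.749 3.765
#> level2 3.820 3.827 3.788 3.756 3.728
#> level3 3.766 3.653 3.805 3.838 3.837
#> level4 3.751 3.836 3.796 3.737 3.802
#> level5 3.788 3.824 3.802 3.827 3.775
#> best levels: pop=50, w=0.9~0.3, c1=1.65, c2=1.65, m=0.2
```

Each cell sums the validation R² of the five runs holding that factor at
that level; the per-column argmax picks the working configuration
(population 50, linearly decaying inertia 0.9→0.3, ...).

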