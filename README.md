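# lagcvr

Voxelwise **haemodynamic lag** and **cerebrovascular reactivity (CVR)**
mapping for stroke fMRI, with a synthetic phantom generator that makes every
stage testable against known ground truth.

## The problem

After a stroke, BOLD fMRI no longer reads out neural activity cleanly: the
vascular insult can delay the haemodynamic response (a *lag*) and blunt its
amplitude. Whether observed lags are a vascular artefact (reduced
reactivity) or reflect neural dynamics matters for every fMRI study of
post-stroke recovery. Answering it requires measuring the two quantities
separately, with matched preprocessing, and correlating them within
lesion-anchored tissue compartments. This package implements that
measurement machinery for researchers analysing resting-state and
breath-hold fMRI in lesioned brains.

## What it computes

* **Lag maps** — for each voxel, the timecourse is cross-correlated with the
  mean grey-matter reference (lesion excluded) at integer shifts
  k ∈ {−4,…,4} frames (±8 s at TR 2 s; 9 positions). Voxels with peak
  r < 0.1 are excluded. The three correlations around the discrete maximum
  are fitted by a parabola; the vertex

  τ̂ = ( m + ½·(r₍ₘ₋₁₎ − r₍ₘ₊₁₎)/(r₍ₘ₋₁₎ − 2rₘ + r₍ₘ₊₁₎) ) · TR

  is the sub-sample lag (positive = the voxel trails the reference).
* **CVR maps** — the end-tidal envelope of the CO2 trace (expiratory peaks,
  linearly interpolated across each breath-hold) is convolved with a
  canonical double-gamma HRF and time-shifted between −15 and +15 s in 0.1 s
  steps; the best-fit delay per voxel is kept and
  CVR = 100·β/intercept (%BOLD/mmHg) taken from the GLM. Voxels with fit
  r < 0.1 (abnormal response) are excluded.
* **Frame QC** — framewise displacement (50 mm rotational radius), >1 mm
  scrubbing, >50% scan exclusion, motion + CSF nuisance regression, 0.01 Hz
  cosine high-pass (with the same confounds projected out of the CVR
  regressor, so the beta is that of the joint GLM).
* **ROIs** — lesion, perilesional shell (≤10 mm from the lesion boundary),
  remote tissue, and their right-hemisphere homologues by sagittal
  reflection, all restricted to grey matter.
* **Statistics** — per-ROI Spearman correlation of lag and CVR with Wilcoxon
  signed-rank group tests (exact distribution with ties up to n = 25;
  Bonferroni α = 0.05/6 = 0.0083), cross-condition spatial Pearson
  correlation of lag maps, one-tailed paired t for longitudinal change, and
  voxelwise group × timepoint OLS ANOVA with Benjamini–Hochberg FDR
  (q = 0.1).
* **Phantoms** — anatomy masks, ground-truth lag/CVR/delay fields, CO2
  traces, motion traces, and resting/breath-hold 4D BOLD built by the same
  forward models the estimators invert.

## Worked example

```r
library(lagcvr)

subject <- simulate_subject(seed = 42)  # phantom: anatomy, truth, BOLD, CO2
result  <- run_subject(subject)         # QC -> lag maps -> CVR -> ROIs -> stats

print(result$lag_rest)
#> <lag_map> reference 'gm_mean', 1735 valid voxels (of 1792 in mask)
#>   lag range: [-8.00, 8.00] s; search grid +/-8 s
print(result$cvr)
#> <cvr_map> 1732 valid voxels (of 1792 in mask); delay grid -15..15 s
#>   CVR median 0.207 %BOLD/mmHg; delay median -0.7 s
result$mean_lag_left_rest
#> [1] -0.1200  # mean lag (s) over lesioned-hemisphere grey matter
result$roi_spearman$perilesional$r
#> [1] -0.002   # lag-CVR Spearman r over 664 perilesional voxels
```

Against the injected truth of this phantom, the resting lag map recovers
the lag field with RMSE 0.081 s (grid step 2 s) and the CVR map recovers
the reactivity field with 11% relative RMSE at temporal SNR 3 — i.e. the
lag estimates are an order of magnitude finer than the sampling, and CVR
is recovered essentially unbiased through the full nuisance-removal
pipeline. The near-zero perilesional Spearman r is correct here: the
phantom's lag and CVR fields are generated independently.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/cli/lagcvr-cli.R simulate    --out phantom/ --seed 1
Rscript inst/cli/lagcvr-cli.R run-subject --out results/ --seed 1
```

## Layout

```
R/                  estimators, phantom generator, pipeline
tests/testthat/     unit, property and acceptance tests (all synthetic)
vignettes/          methods vignette: models, parameters, validation
scripts/acceptance.R
inst/cli/           thin command-line wrapper
```
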