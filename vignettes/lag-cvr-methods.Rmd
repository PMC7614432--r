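---
title: "Measuring haemodynamic lag and cerebrovascular reactivity: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring haemodynamic lag and cerebrovascular reactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagcvr)
```

## The measurement problem

After a stroke, the BOLD signal of fMRI is no longer a clean readout of
neural activity: the vascular insult can delay the haemodynamic response
(a *lag*, or its opposite, a *lead*) and blunt its amplitude. Two separate
quantities capture these effects:

* **Haemodynamic lag** — the signed temporal offset (seconds) of a voxel's
  timecourse relative to a reference signal, conventionally the mean
  grey-matter timecourse with the lesion excluded. Positive values mean the
  voxel trails the reference; negative values mean it leads.
* **Cerebrovascular reactivity (CVR)** — the vasodilatory response capacity
  of the microvasculature, quantified during a breath-hold task as the
  %BOLD signal change per mmHg change in end-tidal CO2 (PETCO2).

This package implements both estimators, the lesion-anchored ROI geometry
and the statistics used to relate them, and a synthetic phantom generator
that makes every stage testable against known ground truth.

## Lag estimation

For each voxel, the timecourse is compared with the reference at the nine
integer shifts $k \in \{-4,\dots,4\}$ frames (at TR = 2 s, $\pm 8$ s in 2 s
increments). The Pearson correlation $r(k)$ is computed over the frame
pairs in which both frames survive motion scrubbing. Voxels whose maximum
correlation over the shift grid stays below $r = 0.1$ are excluded: with no
detectable coupling to the reference, any lag estimate would be noise (in
real data these voxels sit predominantly in white matter).

For accepted voxels the three correlations around the discrete maximum
$(r_{m-1}, r_m, r_{m+1})$ are interpolated by the unique parabola through
them; its vertex abscissa

$$\hat\tau = \left(m + \frac{1}{2}\,
  \frac{r_{m-1}-r_{m+1}}{r_{m-1}-2r_m+r_{m+1}}\right)\cdot TR$$

is the sub-sample lag and its ordinate the peak correlation. Design
choices worth stating explicitly:

* **Boundary maxima are clamped.** If the maximum falls on the edge of the
  grid, the lag is reported as that boundary shift ($\pm 8$ s) with a flag,
  rather than extrapolating the parabola outside the searched range.
* **Perfect peaks are not interpolated.** When $r_m$ is within machine
  tolerance of 1 the voxel is an exact (affine) shifted copy of the
  reference; a parabolic vertex displaced from the grid point would assert
  a correlation above 1, which is impossible. The grid shift itself is
  returned, making recovery of integer-TR lags exact in noise-free
  calibration phantoms. With a composite reference (a mixture of shifted
  copies, as the grey-matter mean always is), peak correlations are below 1
  and the interpolated vertex carries an $O(1/T)$ edge-effect displacement
  of order 0.01–0.05 s on 150-frame runs — far below the 2 s sampling.
* **Three-point fit.** Only the immediate neighbours of the maximum enter
  the parabola; a wider least-squares window would bias the vertex whenever
  the correlogram is asymmetric over $\pm 2$ frames.
* **Degenerate (zero-curvature) triples** return the grid shift with a
  degeneracy flag instead of dividing by zero.
* Each shift requires at least 10 overlapping valid frame pairs; shifts
  with fewer are flagged missing, and voxels whose peak has a missing
  neighbour are treated as boundary cases.

## CVR estimation

The capnograph trace is reduced to its expiratory peaks (end-tidal points):
local maxima separated by at least 2 s, detected on a 0.25 s-smoothed copy
of the trace with a 3 mmHg prominence floor so that measurement noise on
the flat breath-hold segments cannot masquerade as breaths. The end-tidal
points are linearly interpolated onto a 0.1 s grid — in particular linearly
*across* each breath-hold, between the last end-tidal value before and the
first after the hold — and the deviation from the resting baseline (the
median of pre-first-hold end-tidal values) is convolved with a canonical
double-gamma HRF (response peaking at 6 s, undershoot at 16 s, 1:6
amplitude ratio, unit peak).

Because CO2 arrival at the tissue is itself delayed by circulation time and
equipment dead space, the regressor is systematically time-shifted between
$-15$ and $+15$ s in 0.1 s steps. For each delay the voxel is regressed
(OLS, intercept + regressor, valid frames only) on the shifted trace; the
delay maximising the voxel–regressor correlation is kept (ties broken
toward the smallest |delay|, negative first, for determinism). CVR is

$$\mathrm{CVR} = 100 \cdot \beta / \beta_0 \quad
  [\%\mathrm{BOLD}/\mathrm{mmHg}],$$

with $\beta$ the regressor weight and $\beta_0$ the intercept, so the
estimate is invariant to the scanner's arbitrary signal units. Voxels whose
best-fit correlation stays below 0.1 display an abnormal breath-hold
response and are flagged invalid.

The GLM itself carries no drift or nuisance columns; the single-regressor
design makes the delay search exactly equivalent to residual-minimisation.
Instead, when the data have been residualised against motion, CSF and
cosine drift during preprocessing, the *same confound matrix is projected
out of the CO2 regressor* before fitting. By the Frisch–Waugh theorem this
reproduces the beta of the joint GLM; omitting the projection demonstrably
shrinks CVR by tens of percent, because smooth nuisance regressors absorb
part of the slow breath-hold response from the data but not from the
regressor.

## Frame-level quality control

Framewise displacement is the Power-style sum of absolute backward
differences of the six rigid-body parameters, rotations converted to arc
length on a 50 mm sphere. Frames with FD above 1 mm (strictly) are
censored; runs with more than half their frames censored are discarded.
Censored frames are excluded from every fit but retained in the array, so
shift indexing never silently re-aligns. Nuisance regression (six motion
parameters plus the CSF mean timecourse) and high-pass filtering are both
realised as OLS residualisation over the valid frames with the voxel mean
restored; the high-pass basis is the discrete-cosine set spanning
frequencies strictly below 0.01 Hz, which handles censored frames exactly
(a recursive filter would not). The measured stop-band residual at
0.0025 Hz is below 5% and the pass-band at 0.05 Hz is preserved within 1%
on 300 s runs.

## ROI geometry

Six compartments anchor the statistics: the **lesion**; the
**perilesional shell** (grey-matter voxels whose centre lies within 10 mm —
inclusive, centre-to-centre in millimetres, so anisotropic voxels are
handled — of any lesion voxel, excluding the lesion); **remote** left
grey matter outside both; and their right-hemisphere **homologues** by
reflection about the mid-sagittal plane. All six are restricted to grey
matter and to their hemisphere, so the three left compartments partition
left-hemisphere grey matter exactly. Correlation statistics use only
voxels jointly valid in the lag and CVR maps.

## Statistics

* Subject-level lag–CVR association: Spearman rank correlation (average
  ranks) over jointly valid ROI voxels; at least 10 voxels required.
* Group inference: two-sided Wilcoxon signed-rank test of the per-subject
  coefficients against zero, at the Bonferroni-corrected level
  $0.05/6 = 0.0083$. The exact null distribution is used up to $n = 25$,
  computed by convolving the rank contributions — this handles tied
  absolute values, which the textbook no-ties distribution does not — and a
  tie-corrected normal approximation with continuity correction beyond.
* Cross-condition consistency: Pearson correlation of two lag maps over
  jointly valid voxels.
* Longitudinal change: one-tailed paired t-test of hemisphere mean lag
  between visits; identical pairs return the boundary value p = 0.5.
* Voxelwise group analysis: per-voxel OLS fit of lag on group, timepoint
  and their interaction under effect coding, F-test per term, and
  Benjamini–Hochberg step-up FDR control at q = 0.1 per term. The analysis
  mask keeps voxels valid in at least 80% of subjects (a policy parameter);
  each voxel is fitted from the subjects valid there, and voxels whose
  design becomes rank-deficient are dropped. "Mixed-effect ANOVA (ordinary
  least squares)" is implemented exactly as the parenthetical says — a
  fixed-effects OLS ANOVA — with no random-effects machinery.

## The phantom generator

The generator exists so that every estimator above can be validated against
injected truth without any data download. Defaults define the study
conditions and are not tuned per experiment:

| Parameter | Default | Why |
|---|---|---|
| Grid | 20×20×10 voxels, 2 mm isotropic | desk-scale brain with distinct compartments |
| TR / frames | 2 s / 150 (rest), paradigm-limited (breath-hold) | standard EPI timing |
| Paradigm | 6 × (14 s normal + 16 s paced + 15 s hold), 10 s lead-in, 20 s tail | breath-hold protocol; the tail records the final hypercapnic peak |
| Lesion | sphere, radius 6 mm, left hemisphere | ≈0.9 cm³ infarct; keeps all six ROIs non-degenerate |
| Shared signal | band-limited 0.01–0.1 Hz, unit variance | resting-state fluctuation band |
| Coupling amplitude | 1% of baseline | typical resting BOLD fluctuation |
| Baseline | 1000 raw units | arbitrary scanner scale |
| Noise | set from target SNR 3 | subject-quality data |
| Lag field | smooth Gaussian field, SD 1.2 s, clamped ±4 s, demeaned over grey matter | lags are latencies *relative to the grey-matter mean*, so the true field must be centred on the reference |
| CVR field | 0.25 ± 0.08 %BOLD/mmHg, floor 0.05 | healthy grey-matter breath-hold CVR |
| CO2 delay field | smooth, SD 2 s, clamped ±6 s | circulation-time spread |
| CO2 trace | 200 Hz, baseline 40 mmHg, post-hold rise 8 mmHg, 10 s relaxation, 0.25 Hz breathing | typical capnography |
| Lesion voxels | coupling 0, CVR 0 | signal void in infarcted tissue |

The forward models are exactly the estimators' models run in reverse:
resting voxels carry the shared signal shifted by their lag; breath-hold
voxels additionally carry the HRF-convolved end-tidal deviation, scaled by
their CVR and shifted by their CO2 delay, built with the same operators the
estimator uses on the same 0.1 s grid (chosen to match the 0.1 s delay
search step, so fractional-second truths are representable). Breathing
restarts from end-expiration after each hold, so the oscillation phase is
referenced to each breathing segment.

What the phantoms deliberately do **not** contain: cardiac/respiratory
aliasing, vascular-territory geometry, susceptibility dropout, spatially
correlated noise, or any built-in association between the lag field and
the CO2-delay or CVR fields (they are generated independently). Passing
recovery tests therefore demonstrates correctness of the estimation
machinery under the stated noise model — not that patient data will behave
this way. In particular, the cross-condition lag-map correlations observed
in patients are an empirical property of real brains that independent
phantom fields do not reproduce.

## Validation results the test-suite computes

On these phantoms the package's tests and the acceptance script verify,
among other properties: exact recovery of integer-TR lags in the noise-free
calibration construction and RMSE below 0.3 s at SNR 3; CVR relative RMSE
below 2% noise-free (delay error within one 0.1 s search step) and below
10% at SNR 3; per-ROI group mean Spearman correlation within ±0.05 of zero
with independently generated lag and CVR fields, with the Wilcoxon type-I
rate within binomial error of its 0.0083 alpha over 200 replicate cohorts;
detection of a constructed +0.5 s group offset with power above 0.9 after
FDR at q = 0.1, with uniform null p-values; and exact agreement of the
parabolic-vertex, FDR step-up, FD, and exact-Wilcoxon primitives with
brute-force oracles. Problem sizes (20×20×10 grid, 150 frames, 20-subject
cohorts, 200 replicates) are the package's chosen desk-scale defaults.

## Known limitations

* The lag search window (±8 s) clips genuinely longer delays to the
  boundary; such voxels are flagged, not fixed.
* The delay ties and the 0.1 s grid make the CVR delay a step function of
  the data; sub-step precision is not claimed.
* The exact Wilcoxon distribution is computed up to n = 25; beyond that the
  tie-corrected normal approximation is used.
* Hemisphere masks assume a planar mid-sagittal boundary; on odd-sized
  grids the plane column belongs to neither hemisphere.
* The homologue reflection is a rigid mirror; no nonlinear homotopy.
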