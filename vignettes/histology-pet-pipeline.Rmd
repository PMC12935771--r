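---
title: "Voxel-wise histology-to-PET comparison: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise histology-to-PET comparison: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tau PET tracers such as flortaucipir are read as maps of tau pathology,
but part of their retention comes from off-target substrates — ferric
iron stored in ferritin/hemosiderin (prominent in the basal ganglia) and
MAO-B enriched in reactive astrocytes. Disentangling these contributions
requires voxel-to-voxel comparison of quantitative histology against the
PET signal from the same tissue: stained sections are segmented into
positive-pixel masks, converted to metric burden maps, registered
through blockface photographs into MRI/PET space, resolution-matched to
the scanner point-spread function, and regressed against SUVR.

`histopet` implements that pipeline as reusable, tested components, and
pairs it with a fully seeded synthetic cohort generator so that every
stage can be validated against a known answer at desk scale. Real
autopsy/PET datasets of this kind are not publicly deposited, so the
package's empirical claims are about the *method*: exactness of the
counting and rank machinery, closed-loop recovery of known smoothing
kernels and warps, and unbiased recovery of known generative
coefficients.

## The statistical model

Within an ROI of PET-positive voxels, the outcome is the voxel SUVR
$y_v$ and the predictors are the co-registered per-marker burden
fractions $x_{v,m} \in [0,1]$. The fixed model suite is

$$
\begin{aligned}
m_0 &: y \sim \text{p-tau} + \text{iron} + \text{MAO-B} &
m_1 &: y \sim \text{p-tau} + \text{iron} \\
m_2 &: y \sim \text{p-tau} + \text{MAO-B} &
m_3 &: y \sim \text{iron} + \text{MAO-B} \\
m_4 &: y \sim \text{p-tau} &
m_5 &: y \sim \text{iron} \\
m_6 &: y \sim \text{MAO-B} & &
\end{aligned}
$$

all ordinary least squares with intercept, fitted on the identical
complete-row set. When the p-tau marker is absent for a case (a
non-tauopathy), the suite shrinks to $m_3, m_5, m_6$ and $m_3$ becomes
the reference. Models are compared by
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$ with $k = p + 2$ (intercept
and error variance both count); AICc adds $2k(k+1)/(n-k-1)$ and agrees
with AIC to well under 0.1 at the voxel counts in play, so ΔAIC is
reported on plain AIC, defined as $\mathrm{AIC}(m) - \mathrm{AIC}(m_0)$.
Collinearity of the reference model is diagnosed with
$\mathrm{VIF}_j = 1/(1-R^2_j)$. Spearman correlations (Pearson on
average ranks, t-approximate p values) and a tie-corrected normal
Wilcoxon rank-sum (MAO-B inside versus outside white matter) complete
the layer. The prose convention of "mixed models" in this literature
notwithstanding, only the fixed-effects formulas above are specified, so
no random-effects structure is guessed; betas are unstandardized by
default (burdens already share the 0–1 scale) with a `standardize` flag
for z-scored coefficients.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| probability threshold | 0.7 | p ≥ 0.7 is positive for CNN-like maps (p-tau, MAO-B) |
| iron threshold | max-F1 | chosen from the precision–recall curve; ties favor the larger threshold (precision) |
| tile size | 1 mm | percent-positive heatmap cell, approximating MRI resolution |
| PET FWHM | 5 mm | resolution-matching target for burden maps |
| SUVR cutoffs | 1.2 / 1.3 / 1.4 | strict (>) ROI thresholds; 1.2 primary, others sensitivity |
| Dice QC bar | 0.8 | registration quality floor |
| TPS λ | 0 | exact landmark interpolation; raise for very noisy landmarks |

All of these live in the run configuration (`default_config()`), never
hard-coded in the operations.

## The synthetic cohort generator

The phantom is a coronal-slab cartoon: an elliptical tissue region whose
boundary ribbon is cortex, a white-matter interior, and two compact
structures (lentiform nucleus, hippocampus), at 1 mm cells. Marker masks
are drawn at micrometre pitch by thresholding marker-specific textured
Gaussian fields *at the per-region quantile that realizes the requested
positive fraction*: p-tau uses a ~100 µm correlation length (tangle-like
clusters), iron ~15 µm (hard puncta), MAO-B ~300 µm (diffuse astrocytic
texture). Quantile thresholding makes the empirical region density match
the specification essentially exactly while leaving the spatial
character marker-specific; density calibration is therefore a design
property, not a tuning exercise. Default densities place p-tau in
cortex/hippocampus (0.25/0.35), iron in the lentiform nucleus (0.25) and
MAO-B in white matter (0.25) — the canonical on-target and off-target
topographies.

Classifier-like probability maps corrupt the truth with Beta(5,2) draws
on positive pixels and Beta(2,5) on background (point masses give the
noiseless limit). Section distortion is a smooth Gaussian-RBF
displacement field; landmark pairs are spread over a jittered grid (as
an annotator would place them) with 0.1 mm Gaussian measurement jitter
on the blockface side. The PET volume is the generative inverse of
$m_0$: burdens aggregated to 1 mm, smoothed in-plane to the 5 mm scanner
FWHM, combined as $\beta_0 + \sum_m \beta_m x_m$ with i.i.d. Gaussian
noise (SD 0.1 SUVR), plus a constant-activity background region serving
as the cerebellar-like reference for `compute_suvr()`. The generative
coefficients default to $\beta = (1.1, 0.7, 0.4, 0.0)$ — MAO-B
contributes nothing, so the true model structure is $m_1$ and AIC-based
selection can be scored against it.

What the generator does **not** emulate: RGB stain rendering and color
deconvolution, tissue tearing (the warp is smooth and invertible),
through-plane distortion, spatially correlated PET noise, and
partial-volume effects beyond Gaussian smoothing. Passing tests
therefore certify the machinery — counting, thresholding, registration,
resolution matching, model comparison — not the biological fidelity of
any particular segmentation model on real stains.

## Numerical choices

**Percent-positive tiling.** Tiles anchor at the image's top-left
corner; a pixel belongs to the tile containing its center. Edge tiles
with less than half a full tile's pixel budget are invalid rather than
silently diluted.

**Smoothness estimation.** For a stationary field with variance $s^2$
and first-difference variance $d^2$ along an axis,
$\mathrm{FWHM} = \Delta \cdot \sqrt{-2\ln 2 / \ln(1 - d^2/(2s^2))}$.
Axes with $d^2 \ge 2s^2$ (white noise) are inestimable and treated as
unsmoothed. On a 48-cell grid the estimator is noticeably noisy at 5 mm
FWHM (few independent resels), which is why the pipeline reports
per-slice match error as a diagnostic rather than enforcing the 2%
tolerance there; the closed-loop tolerance is verified on 256² fields.

**Blur-to-FWHM.** The incremental kernel starts at
$\sqrt{\text{target}^2 - \text{current}^2}$ (Gaussian quadrature
composition), candidates that overshoot the target by more than the
tolerance are rejected and the increment halved, and increments below a
fifth of a cell terminate the loop with a warning flag. Convolutions are
separable with kernels renormalized over valid cells, so [0,1] fields
stay in [0,1] at edges and holes.

**TPS registration.** Kernel $U(r) = r^2\log r$ with $U(0)=0$; the
radial coefficients satisfy the zero-sum and zero-first-moment side
conditions by construction. Resampling is inverse mapping of output cell
centers, so the fitted transform maps output space to source space (fit
on swapped landmark pairs). With exactly three non-collinear landmarks
the solution is purely affine. Deformable (SyN-style) refinement is out
of scope; the closed-loop tests show dense-landmark TPS reaches Dice
≥ 0.95 on the phantom, and the stage boundary leaves room to insert a
refiner.

**Conventions.** Millimetre coordinates, origin at the top-left cell
center, 0-based, (row, col) = (y, x); volumes are (row, col, slice)
arrays. SUVR ROI thresholds are strict (a voxel exactly at threshold is
excluded). Two empty masks have Dice 1 with a warning flag. Missing
markers stay missing — never zero-imputed — and shrink the model suite.

## The recovery study

`beta_recovery_study()` fixes one synthetic design (48 × 48 mm, seven
1 mm-spaced sections, truth masks at 100 µm pitch, burdens smoothed to
5 mm — about 3,000 ROI voxels) and replicates the PET noise 50 times.
The ROI is thresholded on the *noiseless* SUVR: thresholding the noisy
outcome would truncate the error distribution and bias OLS — a selection
effect, not an estimation failure — whereas with a fixed design the
±3 SE recovery, 95% CI coverage, and AIC ranking of $m_1$ are the
properties classical theory predicts, and the ones the study measures.
The full pipeline run additionally reports measured-path coefficient
estimates, where registration and segmentation error attenuate the betas
— the realistic regime, reported as diagnostics rather than asserted.

## Problem sizes

Defaults are chosen for interactive use: pipeline phantom 48 × 48 mm at
50 µm pixel pitch with three sections (a full run takes tens of seconds
on one core), recovery study as above, closed-loop smoothing checks on
256² fields, registration loops at 200 µm pitch. The histology pitch is
a configuration knob — all downstream math is pitch-agnostic — with the
generator's own default at 10 µm per pixel.

## Known limitations

Single-warp-per-section registration (real protocols stain three
adjacent sections, each with its own distortion); in-plane-only
resolution matching (a
three-slice slab cannot support 5 mm through-plane smoothing); OLS
inference that ignores spatial autocorrelation of neighboring voxels
(standard errors are optimistic on real data in exactly the way the
field's voxel-wise regressions are); and a deliberately simple ridge
logistic pixel classifier, which stands in for trained CNN segmentation
only at the interface level.
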