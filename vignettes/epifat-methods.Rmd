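---
title: "Quantifying epicardial fat from cine Dixon MRI: models and methods"
author: "epifat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epicardial fat from cine Dixon MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifat)
```

## Scope and model

`epifat` implements a threshold-based epicardial adipose tissue (EAT)
volumetry pipeline for water–fat separated cardiac MRI, together with a
synthetic cine Dixon phantom that stands in for patient scans and the
agreement statistics used in observer-variability studies. The chain is

*simulate (or ingest) → optional two-point Dixon reconstruction →
fat-fraction map → cine frame selection → FF thresholding inside a
per-slice epicardial ROI → per-slice and total volumes → agreement
statistics.*

The physics of acquisition (pulse sequences, compressed-sensing
reconstruction, respiratory gating, contrast pharmacokinetics) is out of
scope; the package starts from registered water/fat magnitude volumes or
from two complex echoes under an idealized signal model.

### Fat fraction and segmentation

Per voxel, the fat fraction is

$$\mathrm{FF} = \frac{F}{F + W},$$

clamped to $[0,1]$. Voxels whose total signal $F+W$ falls at or below a
small cutoff `eps` (default $10^{-6}$ of the channel maximum) are set to
$\mathrm{FF}=0$: a signal void carries no evidence of fat, and the
convention guarantees such voxels fall below any classification
threshold, consistent with the removal of low-FF chamber and
great-vessel voxels. A voxel is classified as epicardial fat iff it lies
inside the per-slice outer epicardial ROI, its slice lies within the
analysis slice range, and $\mathrm{FF}$ is **strictly** greater than the
threshold (default 0.35, i.e. "over 35 %" — the boundary value itself is
excluded). Volumes are counts times the voxel volume; the patient total
integrates the analysis slice range only. In a clinical stack that range
runs from the last slice showing apical myocardium to the first slice
showing the pulmonary bifurcation — anatomical judgements the package
treats as explicit inputs (the phantom supplies them in its ground
truth).

Volumes are computed on whatever grid the FF map lives on. Whether a
clinical analysis should integrate on the acquired
($1.5\times1.5\times3.0$ mm) or reconstructed
($0.8\times0.8\times1.5$ mm) grid is a protocol choice; the spacing is an
argument everywhere, and the phantom defaults to the acquired grid while
the observer-study cohort uses 1.5 mm reconstructed-thickness slices so
that a whole heart spans on the order of 100 slices.

### Frame matching

Cine segmentation is performed on a single timeframe, matched to the
trigger delay of a reference single-phase scan: `selectFrame()` returns
the frame whose time after the R-wave minimizes
$|t_\mathrm{frame} - \mathrm{TD}|$, ties breaking to the earlier frame.
With 15 frames at 65 ms and TD = 730 ms this is the frame at 715 ms.
Indices are 1-based throughout, following R convention.

### Two-point Dixon separation

The synthesis model per voxel and echo time is

$$S(TE) = \bigl(W + F\,e^{i\theta(TE)}\bigr)\,e^{i 2\pi \psi TE},\qquad
  \theta(TE) = 2\pi\,\Delta f_{fw}\,TE,$$

with $\Delta f_{fw}$ the water–fat shift (default $-220$ Hz, the
3.5 ppm main fat peak at 1.5 T) and $\psi$ a smooth off-resonance field
map. `dixonSeparate()` inverts this: after demodulating a supplied
$\psi$, the four real equations (real and imaginary parts of two echoes)
are solved for the two real unknowns $W, F \ge 0$ by least squares in
closed form; negative solutions, which arise only under noise, are
clipped to zero. On noiseless input generated with the same $\psi$ the
inversion is exact to machine precision. Field-map *estimation* from
data (region growing, graph cuts) is deliberately not implemented — the
package needs a correct reference inversion, not a vendor
reconstruction; $\psi$ is an input. Echo pairs with
$\theta_1 \equiv \theta_2 \pmod{2\pi}$ are rejected as unable to
separate water from fat. Multi-peak fat modeling and $T_2^*$ (IDEAL)
fitting are non-goals.

## The phantom

The phantom is a stylized nested-ellipsoid heart, not a deformable human
atlas: blood pool inside a myocardial shell, wrapped in an epicardial
fat rind, a one-voxel parietal pericardium, a static paracardial fat
slab lateral to the heart, and lung filling the rest of an outer thorax
ellipsoid. It exists to exercise every pipeline stage with exact ground
truth and to reproduce the epicardial-vs-paracardial *motion contrast*;
it does not attempt realistic anatomy.

Default conditions emulate the contrast-enhanced axial whole-heart
protocol: $64\times64\times40$ voxels at $1.5\times1.5\times3.0$ mm, 15
cine frames at 65 ms over a 1000 ms cycle. Motion is a smooth systolic
analogue applied to the heart-attached compartments only: longitudinal
(apical) displacement $d(t) = A\,\sin^2(\pi t/n)$ with $A = 10$ mm by
default (a typical AV-plane descent), plus an in-plane radial
contraction $1 - c\,\sin^2(\pi t/n)$ with $c = 0.1$. No motion equations
are prescribed by the underlying clinical protocol; the $\sin^2$ ramp is
this package's choice of a smooth, cycle-periodic systolic profile. The
paracardial slab is placed beyond the heart's lateral extent with a
clearance gap, so purely longitudinal motion can never reach it — its
voxel set is frame-invariant by construction, which is also a tested
invariant.

Signals: each tissue has a total amplitude $S$ and a true fat fraction
$\mathrm{FF}$, from which $W = S(1-\mathrm{FF})$ and
$F = S\,\mathrm{FF}$ are derived — so the noiseless phantom satisfies
$F/(F+W) = \mathrm{FF}$ exactly, by construction. Defaults: blood pool
$S=1.0$ (bright water, the contrast-enhancement analogue),
$\mathrm{FF}=0.05$; myocardium $0.6/0.10$; epicardial and paracardial
fat $1.0/0.80$; pericardium $0.5/0.10$; lung $0.1/0$. Fat at
$\mathrm{FF}=0.8$ and all non-fat tissue below 0.35 makes the
classification separable, so noiseless volume recovery is exact.

Noise is additive zero-mean Gaussian per channel and frame (magnitude
images at moderate SNR; the Rician floor is ignored), seeded from the
spec's single `seed` — all randomness flows from it, and distinct seeds
change only the noise, never the labels. The acquisitions' real SNR is
not documented in the protocol, so the default is noiseless and tests
use 2 % and 5 % of the tissue signal where a noise level is needed.

Known gaps versus real data: no partial-volume fractions beyond
rasterization, no intensity inhomogeneity, no motion artifacts or
through-plane deformation, no Rician bias, ROIs derived from geometry
rather than human tracing. Passing tests therefore demonstrate the
*correctness of the computational chain* under known truth, not clinical
accuracy on patient scans.

## Observer-variability simulation

The observer study design mirrors the clinical one: 5 phantom
"patients" (heart sizes scaled 0.85–1.15), a ~100-slice 1.5 mm stack,
every 10th slice analysed — about 10 slices per patient, i.e. ~50 data
points per method. Each simulated observer re-draws the epicardial ROI
as a perturbation of the reference boundary: per slice, the ROI is
morphologically dilated or eroded (direction uniform at random) with a
disc of radius equal to the jitter amplitude $j$. Amplitude is defined
as the *fixed* radius rather than a radius drawn from $\{0..j\}$ so that
the per-slice volume error scales with $j$ by construction and the
agreement between two independent observers degrades monotonically as
$j$ grows; at $j=0$ both observers reproduce the reference segmentation
and the ICC is exactly 1. `observerStudyICC()` reports the ICC across a
vector of amplitudes.

## Agreement statistics

* **Bland–Altman**: differences $x-y$ (first minus second measurement),
  bias = mean, spread = sample SD ($n-1$), limits of agreement at
  $\pm1.96$ SD.
* **Percent error**: each per-slice difference divided by the patient's
  total fat volume, scaled to percent. The denominator is the
  per-patient mean of the two compared measurements' totals; per-slice
  percentage errors reported in the literature do not always state their
  basis, so this choice is documented rather than claimed to replicate
  any published numbers.
* **ICC**: two-way random-effects, absolute-agreement, single-measures
  ICC(2,1) by default,
  $(MS_R - MS_E)\,/\,(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$
  with $k=2$; the consistency form ICC(3,1) is selectable. The clinical
  convention rarely states the model; absolute agreement is the standard
  choice for observer studies where systematic offsets should count
  against agreement. Mean squares come from the two-way ANOVA
  (`stats::aov`); the formula is validated in the tests against an
  independent sums-of-squares computation. Categories: poor $<0.5$,
  moderate $[0.5, 0.75)$, good $[0.75, 0.9)$, excellent $\ge 0.9$ — the
  verbal convention ("between … and …") is boundary-ambiguous, so each
  boundary is assigned to the upper class, documented here.
* **BSA**: Mosteller $\sqrt{hw/3600}$ by default (the commonly used
  formula when none is stated); Du Bois selectable.
* **Paired tests**: paired t-test and exact Wilcoxon signed-rank;
  significance flagged at $P<0.05$. Identical paired samples give
  $p = 1$ for the t-test by convention; all-zero differences are a
  degenerate input for the signed-rank test and raise an error.

## Numerical choices and degenerate inputs

* FF void cutoff `eps`: $10^{-6}$ of the channel maximum; `eps` must be
  positive.
* Threshold comparisons are strict (`>`): total volume is non-increasing
  in the threshold, and a uniform map exactly at the threshold yields an
  empty segmentation.
* Frame-selection ties break to the earlier frame (`which.min`).
* Dixon: the closed-form $2\times2$ normal equations have determinant
  $4 - (\cos\theta_1+\cos\theta_2)^2$; degenerate echo spacings are
  rejected before solving. Negative LS solutions clip to 0.
* Polygon ROIs rasterize by the even-odd rule on voxel centres; polygon
  vertices are given in 1-based voxel coordinates.
* Phantom sizing is validated innermost-shell-first so the error names
  the first shell that does not fit the grid (including the apical
  motion allowance).
* Anatomy labels paint outermost-to-innermost, so every voxel carries
  exactly one tissue label.

## Problem sizes

The test suite and the acceptance script run compact configurations
chosen to exercise the full chain: the default $64\times64\times40$,
15-frame phantom for round-trip and recovery checks (~2.5 M voxels per
channel), a $40\times32\times20$, 4-frame toy phantom for unit tests,
the 5-patient $64\times64\times110$ single-frame cohort for the observer
study, 10 noise seeds for the Monte-Carlo recovery bound, and 100
randomized small volumes for the property checks. These sizes make the
whole suite run in well under a minute per file while leaving every
assertion at full precision.

## Limitations

Single fat peak, no $T_2^*$, field map assumed known, stylized anatomy
and motion, Gaussian (not Rician) noise, geometric ROIs. The statistics
module assumes exactly two measurements per comparison (two repeats or
two observers); mixed-effects extensions and multiple-testing correction
are out of scope.
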