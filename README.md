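# epifat

Quantification of epicardial adipose tissue from cine Dixon water–fat
cardiac MRI, with a synthetic cine phantom and observer-agreement
statistics.

## The problem

Epicardial fat — the adipose depot between the myocardium and the
parietal pericardium — is linked to atrial fibrillation, coronary artery
disease and ventricular dysfunction, and there is growing interest in
measuring its volume. Dixon water–fat MRI depicts it well, but the
epicardial border is hard to separate from the neighbouring *paracardial*
fat (outside the pericardium) on a single-phase scan. Time-resolved
(cine) Dixon imaging exploits the motion contrast between the two
depots: epicardial fat moves with the heart (notably with the
atrioventricular-plane descent in systole) while paracardial fat is
nearly static.

`epifat` implements the quantification pipeline around that idea for
people developing or validating such protocols:

1. **Phantom** — a seeded synthetic cine Dixon dataset (nested-ellipsoid
   heart with a moving epicardial fat rind, a one-voxel pericardium and a
   static paracardial slab) with known ground truth
   (`PhantomSpec()`, `buildAnatomy()`, `renderDixon()`).
2. **Dixon separation** — a reference two-point least-squares inversion
   of the complex gradient-echo signal model
   `S(TE) = (W + F·e^{iθ(TE)})·e^{i2πψTE}` (`synthesizeEchoes()`,
   `dixonSeparate()`).
3. **Fat-fraction mapping** — `FF = F/(F+W)` per voxel, with a
   signal-void convention mapping empty voxels to FF = 0
   (`fatFraction()`).
4. **Segmentation & volumetry** — cine frame selection by trigger delay,
   FF thresholding (default 0.35, strict `>`) inside per-slice outer
   epicardial ROIs, and per-slice/total volume integration
   (`selectFrame()`, `classifyFat()`, `quantifyVolume()`,
   `subsampleSlices()`).
5. **Agreement statistics** — Bland–Altman limits of agreement,
   per-slice measurement error in ml and % of the patient total,
   ICC(2,1)/(3,1) with the poor/moderate/good/excellent categories at
   0.5/0.75/0.9, BSA-indexed regression on BMI, and paired t /
   signed-rank tests (`blandAltman()`, `icc()`, `observerAgreement()`,
   `regressBMI()`, `pairedCompare()`).
6. **Simulated observer study** — ROI boundary jitter of controlled
   amplitude re-quantified over a phantom cohort, reproducing the
   inter-observer analysis design (`jitterROI()`,
   `simulateObserverStudy()`, `observerStudyICC()`).

## Worked example

```r
library(epifat)

## a cine Dixon phantom at the acquired geometry (1.5 x 1.5 x 3.0 mm,
## 15 frames at 65 ms), with 2% channel noise
spec    <- PhantomSpec(noiseSigma = 0.02, seed = 42L)
phantom <- renderDixon(buildAnatomy(spec), spec)

## match the cine frame to a 730 ms trigger delay
frame <- selectFrame(frameTimesMs(phantom$series), 730)
#> frame 12, acquired at 715 ms

## fat fraction, threshold segmentation in the epicardial ROI, volumetry
ffm   <- fatFraction(phantom$series, frame = frame)
roi   <- groundTruthROI(phantom$truth)[[frame]]
fat   <- classifyFat(ffm, roi, threshold = 0.35)
quant <- quantifyVolume(fat, spacingMm(phantom$series),
                        sliceRange(roi), threshold = 0.35)
quant
#> FatQuantification: 26 slices, total 71.87 ml (threshold 0.35 )
trueVolumeMl(phantom$truth)[frame]
#> [1] 71.874

## a simulated two-observer study: 5 phantom patients, every 10th slice,
## 2-voxel boundary jitter
tb  <- simulateObserverStudy(jitterVox = 2, nPatients = 5L, step = 10L,
                             seed = 7L)
blandAltman(tb$obs1_ml, tb$obs2_ml, icc = icc(tb$obs1_ml, tb$obs2_ml))
#> AgreementResult (n = 46 pairs)
#>   bias -0.026 ml, SD 0.406 ml, LoA [-0.821, 0.769]
#>   ICC 0.402 (poor)
```

The segmented total (71.87 ml) matches the phantom's ground-truth rind
volume at that cardiac phase; under boundary jitter the per-slice
agreement degrades, which is what the ICC and the limits of agreement
quantify.

A thin shell interface over the same functions is provided in
`inst/cli/epifat.R`
(`simulate | recon | ff | quantify | stats | run`), e.g.

```sh
Rscript inst/cli/epifat.R run --out out/ --seed 3
```

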