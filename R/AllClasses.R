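#' @import methods
NULL

#' Tissue label codes used by the cardiac phantom
#'
#' Integer codes for the seven phantom compartments. The heart-attached
#' compartments (blood pool, myocardium, epicardial fat, pericardium) move
#' with the cardiac cycle; the paracardial fat, lung and background are
#' static.
#'
#' @format Named integer vector of length 7.
#' @export
tissueLabels <- c(
  background      = 0L,
  lung            = 1L,
  blood_pool      = 2L,
  myocardium      = 3L,
  epicardial_fat  = 4L,
  pericardium     = 5L,
  paracardial_fat = 6L
)

.cardiacLabels <- c("blood_pool", "myocardium", "epicardial_fat", "pericardium")

#' PhantomSpec: parameters of the synthetic cine Dixon phantom
#'
#' Describes the acquisition geometry, tissue signal model, cardiac motion
#' and noise of the synthetic whole-heart cine Dixon dataset. Defaults
#' follow a typical contrast-enhanced 1.5 T axial whole-heart protocol:
#' acquired voxel 1.5 x 1.5 x 3.0 mm, 15 cine frames at 65 ms temporal
#' resolution.
#'
#' @slot gridShape integer(3), voxels per axis (x, y, z).
#' @slot voxelSpacingMm numeric(3), voxel spacing in mm per axis.
#' @slot nFrames integer(1), cine frames per cardiac cycle.
#' @slot rrIntervalMs numeric(1), cardiac cycle length in ms.
#' @slot temporalResolutionMs numeric(1), time between cine frames in ms.
#' @slot tissueFF named numeric, true fat fraction per tissue label, in [0,1].
#' @slot tissueSignal named numeric, noiseless total signal (W+F) per tissue.
#' @slot bloodRadiiMm numeric(3), semi-axes of the blood-pool ellipsoid (mm).
#' @slot wallThicknessMm numeric(1), myocardial shell thickness (mm).
#' @slot fatThicknessMm numeric(1), epicardial fat rind thickness (mm).
#' @slot pericardiumThicknessMm numeric(1), pericardial shell thickness (mm).
#' @slot motionAmplitudeMm numeric(1), peak AV-plane longitudinal
#'   displacement of the cardiac compartments (mm).
#' @slot contractionFraction numeric(1), peak in-plane radial contraction of
#'   the cardiac compartments, in [0, 0.5).
#' @slot noiseSigma numeric(1), additive Gaussian noise SD in signal units,
#'   applied independently per channel and frame.
#' @slot fieldmapHz numeric(1), amplitude of the smooth off-resonance field
#'   map used when synthesizing complex echoes (0 = no field map).
#' @slot seed integer(1), seed governing all phantom randomness.
#' @export
setClass("PhantomSpec", representation(
  gridShape = "integer",
  voxelSpacingMm = "numeric",
  nFrames = "integer",
  rrIntervalMs = "numeric",
  temporalResolutionMs = "numeric",
  tissueFF = "numeric",
  tissueSignal = "numeric",
  bloodRadiiMm = "numeric",
  wallThicknessMm = "numeric",
  fatThicknessMm = "numeric",
  pericardiumThicknessMm = "numeric",
  motionAmplitudeMm = "numeric",
  contractionFraction = "numeric",
  noiseSigma = "numeric",
  fieldmapHz = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (length(object@voxelSpacingMm) != 3L || any(object@voxelSpacingMm <= 0))
    msg <- c(msg, "voxelSpacingMm must be 3 positive values")
  if (object@nFrames < 1L)
    msg <- c(msg, "nFrames must be >= 1")
  if (object@temporalResolutionMs <= 0)
    msg <- c(msg, "temporalResolutionMs must be > 0")
  if (!setequal(names(object@tissueFF), names(tissueLabels)))
    msg <- c(msg, "tissueFF must be named for every tissue label")
  else if (any(object@tissueFF < 0 | object@tissueFF > 1))
    msg <- c(msg, "tissueFF values must lie in [0, 1]")
  if (!setequal(names(object@tissueSignal), names(tissueLabels)))
    msg <- c(msg, "tissueSignal must be named for every tissue label")
  else if (any(object@tissueSignal < 0))
    msg <- c(msg, "tissueSignal values must be >= 0")
  if (object@motionAmplitudeMm < 0)
    msg <- c(msg, "motionAmplitudeMm must be >= 0")
  if (object@contractionFraction < 0 || object@contractionFraction >= 0.5)
    msg <- c(msg, "contractionFraction must lie in [0, 0.5)")
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be >= 0")
  if (length(object@bloodRadiiMm) != 3L || any(object@bloodRadiiMm <= 0))
    msg <- c(msg, "bloodRadiiMm must be 3 positive values")
  if (any(c(object@wallThicknessMm, object@fatThicknessMm,
            object@pericardiumThicknessMm) <= 0))
    msg <- c(msg, "shell thicknesses must be > 0")
  if (length(msg)) msg else TRUE
})

#' TissueLabelMap: per-frame tissue segmentation of the phantom
#'
#' @slot labels 4D integer array (x, y, z, frame) of \code{\link{tissueLabels}}
#'   codes; every voxel carries exactly one label.
#' @slot spacingMm numeric(3), voxel spacing in mm.
#' @export
setClass("TissueLabelMap", representation(
  labels = "array",
  spacingMm = "numeric"
))

setValidity("TissueLabelMap", function(object) {
  if (length(dim(object@labels)) != 4L)
    return("labels must be a 4D (x, y, z, frame) array")
  if (!all(object@labels %in% tissueLabels))
    return("labels contains codes outside the tissue label set")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    return("spacingMm must be 3 positive values")
  TRUE
})

#' DixonSeries: registered water/fat cine volumes
#'
#' @slot water,fat 4D numeric arrays (x, y, z, frame), non-negative.
#' @slot spacingMm numeric(3), voxel spacing in mm.
#' @slot frameTimesMs numeric, acquisition time of each frame after the
#'   R-wave (ms), strictly increasing.
#' @export
setClass("DixonSeries", representation(
  water = "array",
  fat = "array",
  spacingMm = "numeric",
  frameTimesMs = "numeric"
))

setValidity("DixonSeries", function(object) {
  dW <- dim(object@water); dF <- dim(object@fat)
  if (length(dW) != 4L || !identical(dW, dF))
    return("water and fat must be 4D arrays of identical shape")
  if (dW[4L] != length(object@frameTimesMs))
    return("frameTimesMs length must equal the number of frames")
  if (length(object@frameTimesMs) > 1L && any(diff(object@frameTimesMs) <= 0))
    return("frameTimesMs must be strictly increasing")
  if (min(object@water) < 0 || min(object@fat) < 0)
    return("water and fat images must be non-negative")
  TRUE
})

#' EpicardialROISet: per-slice outer epicardial boundaries for one frame
#'
#' The region of interest is the filled area inside the manually (or
#' synthetically) traced outer epicardial boundary, stored as a per-slice
#' binary mask, together with the axial analysis slice range (apex to
#' pulmonary-bifurcation analogue).
#'
#' @slot mask 3D logical array (x, y, z); \code{TRUE} inside the boundary.
#' @slot sliceRange integer(2), inclusive 1-based (low, high) z indices of
#'   the analysis range.
#' @slot frameIndex integer(1), 1-based cine frame the ROI belongs to.
#' @export
setClass("EpicardialROISet", representation(
  mask = "array",
  sliceRange = "integer",
  frameIndex = "integer"
))

setValidity("EpicardialROISet", function(object) {
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    return("mask must be a 3D logical array")
  sr <- object@sliceRange
  if (length(sr) != 2L || sr[1L] > sr[2L])
    return("sliceRange must be an increasing (low, high) pair")
  if (sr[1L] < 1L || sr[2L] > dim(object@mask)[3L])
    return("sliceRange outside the volume extent")
  TRUE
})

#' GroundTruth: phantom reference segmentation and volumes
#'
#' @slot fatMask 4D logical array, epicardial fat voxels per frame.
#' @slot trueVolumeMl numeric, epicardial fat volume per frame (ml).
#' @slot roi list of \code{\linkS4class{EpicardialROISet}}, one per frame.
#' @slot sliceRange integer(2), the analysis range (union over frames).
#' @export
setClass("GroundTruth", representation(
  fatMask = "array",
  trueVolumeMl = "numeric",
  roi = "list",
  sliceRange = "integer"
))

setValidity("GroundTruth", function(object) {
  d <- dim(object@fatMask)
  if (length(d) != 4L) return("fatMask must be 4D")
  if (length(object@trueVolumeMl) != d[4L])
    return("trueVolumeMl must have one entry per frame")
  if (length(object@roi) != d[4L])
    return("roi must hold one EpicardialROISet per frame")
  TRUE
})

#' EchoPair: two complex gradient-echo volumes for Dixon separation
#'
#' @slot s1,s2 complex arrays of identical shape, the signals at the two
#'   echo times.
#' @slot te1Ms,te2Ms numeric(1), echo times in ms, \code{te2Ms > te1Ms}.
#' @slot deltaFHz numeric(1), assumed water-fat frequency shift in Hz
#'   (about -220 Hz at 1.5 T for the 3.5 ppm main fat peak).
#' @export
setClass("EchoPair", representation(
  s1 = "array",
  s2 = "array",
  te1Ms = "numeric",
  te2Ms = "numeric",
  deltaFHz = "numeric"
))

setValidity("EchoPair", function(object) {
  if (!identical(dim(object@s1), dim(object@s2)))
    return("s1 and s2 must have identical shape")
  if (!is.complex(object@s1) || !is.complex(object@s2))
    return("s1 and s2 must be complex arrays")
  if (object@te1Ms <= 0 || object@te2Ms <= object@te1Ms)
    return("echo times must satisfy 0 < te1Ms < te2Ms")
  TRUE
})

#' FatFractionMap: per-voxel fat fraction FF = F/(F+W)
#'
#' @slot ff 3D numeric array of values in [0, 1].
#' @slot spacingMm numeric(3), voxel spacing in mm.
#' @slot frameTimeMs numeric(1), cardiac phase of the source frame (ms;
#'   \code{NA} when unknown).
#' @export
setClass("FatFractionMap", representation(
  ff = "array",
  spacingMm = "numeric",
  frameTimeMs = "numeric"
))

setValidity("FatFractionMap", function(object) {
  if (length(dim(object@ff)) != 3L)
    return("ff must be a 3D array")
  if (min(object@ff) < 0 || max(object@ff) > 1)
    return("ff values must lie in [0, 1]")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    return("spacingMm must be 3 positive values")
  TRUE
})

#' FatQuantification: per-slice and total epicardial fat volume
#'
#' @slot perSlice data.frame with columns \code{slice}, \code{count},
#'   \code{volume_ml}; one row per slice of the analysis range.
#' @slot totalMl numeric(1), sum of per-slice volumes over the range.
#' @slot threshold numeric(1), FF cutoff used for classification.
#' @slot voxelVolumeMm3 numeric(1), product of the voxel spacings.
#' @export
setClass("FatQuantification", representation(
  perSlice = "data.frame",
  totalMl = "numeric",
  threshold = "numeric",
  voxelVolumeMm3 = "numeric"
))

setValidity("FatQuantification", function(object) {
  req <- c("slice", "count", "volume_ml")
  if (!all(req %in% names(object@perSlice)))
    return("perSlice must have columns slice, count, volume_ml")
  if (any(object@perSlice$count < 0))
    return("counts must be >= 0")
  if (abs(object@totalMl - sum(object@perSlice$volume_ml)) >
      1e-8 * max(1, object@totalMl))
    return("totalMl must equal the sum of per-slice volumes")
  TRUE
})

#' AgreementResult: Bland-Altman and ICC summary of paired measurements
#'
#' @slot meanDiffMl,sdDiffMl mean and sample SD of per-slice differences (ml).
#' @slot loaLow,loaHigh 95\% limits of agreement, mean +/- 1.96 SD.
#' @slot meanDiffPct,sdDiffPct percent-scale error summaries (\code{NA}
#'   when no patient totals were supplied).
#' @slot icc intraclass correlation coefficient (\code{NA} when not computed).
#' @slot iccCategory agreement category (poor/moderate/good/excellent).
#' @slot nPairs number of paired observations.
#' @export
setClass("AgreementResult", representation(
  meanDiffMl = "numeric",
  sdDiffMl = "numeric",
  loaLow = "numeric",
  loaHigh = "numeric",
  meanDiffPct = "numeric",
  sdDiffPct = "numeric",
  icc = "numeric",
  iccCategory = "character",
  nPairs = "integer"
))

setValidity("AgreementResult", function(object) {
  tol <- 1e-8 * max(1, abs(object@meanDiffMl), abs(object@sdDiffMl))
  if (abs(object@loaLow - (object@meanDiffMl - 1.96 * object@sdDiffMl)) > tol)
    return("loaLow must equal meanDiff - 1.96*sd")
  if (abs(object@loaHigh - (object@meanDiffMl + 1.96 * object@sdDiffMl)) > tol)
    return("loaHigh must equal meanDiff + 1.96*sd")
  if (!is.na(object@icc) && (object@icc < -1 || object@icc > 1))
    return("icc must lie in [-1, 1]")
  TRUE
})
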