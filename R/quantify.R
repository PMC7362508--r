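#' @include AllClasses.R roi.R
NULL

#' Select the cine frame matching a trigger delay
#'
#' Returns the 1-based index of the frame whose acquisition time is
#' nearest to the trigger delay of the reference single-phase scan; ties
#' break toward the earlier frame.
#'
#' @param frameTimesMs strictly increasing frame times (ms).
#' @param triggerDelayMs non-negative trigger delay (ms).
#' @return Integer frame index (1-based).
#' @examples
#' selectFrame(seq(0, 910, by = 65), 730)  # frame 12, at 715 ms
#' @export
selectFrame <- function(frameTimesMs, triggerDelayMs) {
  if (!length(frameTimesMs))
    stop("frameTimesMs must be non-empty")
  if (length(frameTimesMs) > 1L && any(diff(frameTimesMs) <= 0))
    stop("frameTimesMs must be strictly increasing")
  if (triggerDelayMs < 0)
    stop("triggerDelayMs must be >= 0")
  which.min(abs(frameTimesMs - triggerDelayMs))
}

#' Classify epicardial fat voxels by FF thresholding within the ROI
#'
#' A voxel is classified as epicardial fat iff it lies inside the
#' per-slice ROI, its slice lies within the ROI's analysis slice range,
#' and its fat fraction is strictly greater than the threshold ("over"
#' the cutoff; the boundary value itself is excluded). The default
#' threshold of 0.35 removes the low-FF voxels of the cardiac chambers
#' and great vessels.
#'
#' @param ff a \code{\linkS4class{FatFractionMap}} or 3D array in [0, 1].
#' @param roi an \code{\linkS4class{EpicardialROISet}}.
#' @param threshold FF cutoff in (0, 1); default 0.35.
#' @return 3D logical array of fat voxels.
#' @export
classifyFat <- function(ff, roi, threshold = 0.35) {
  if (is(ff, "FatFractionMap")) ff <- ff@ff
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  if (!identical(dim(ff), dim(roi@mask)))
    stop("FF map and ROI mask shapes differ")
  covered <- which(apply(roi@mask, 3L, any))
  bad <- covered[covered > dim(ff)[3L]]
  if (length(bad))
    stop("ROI slice ", bad[1L], " outside the volume extent")
  mask <- ff > threshold & roi@mask
  sr <- roi@sliceRange
  keep <- array(FALSE, dim = dim(mask))
  keep[, , sr[1L]:sr[2L]] <- TRUE
  mask & keep
}

#' Integrate a fat mask into per-slice and total volumes
#'
#' Per-slice voxel counts are converted to millilitres with the voxel
#' volume (product of the spacings, in mm^3); the patient total is the
#' sum over the analysis slice range only.
#'
#' @param mask 3D logical fat mask.
#' @param spacingMm voxel spacing in mm (3 positive values).
#' @param sliceRange inclusive 1-based (low, high) analysis range;
#'   defaults to the full z extent.
#' @param threshold FF cutoff recorded in the result (metadata only).
#' @return A \code{\linkS4class{FatQuantification}}.
#' @examples
#' m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- TRUE
#' quantifyVolume(m, c(0.8, 0.8, 1.5))  # 1000 voxels -> 0.96 ml
#' @export
quantifyVolume <- function(mask, spacingMm, sliceRange = NULL,
                           threshold = NA_real_) {
  spacingMm <- as.numeric(spacingMm)
  if (length(spacingMm) != 3L || any(spacingMm <= 0))
    stop("spacingMm must be 3 positive values")
  mask <- as.array(mask) > 0
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  nz <- dim(mask)[3L]
  if (is.null(sliceRange)) sliceRange <- c(1L, nz)
  sliceRange <- as.integer(sliceRange)
  if (sliceRange[1L] < 1L || sliceRange[2L] > nz ||
      sliceRange[1L] > sliceRange[2L])
    stop("invalid sliceRange")
  voxMm3 <- prod(spacingMm)
  slices <- sliceRange[1L]:sliceRange[2L]
  counts <- vapply(slices, function(z) sum(mask[, , z]), integer(1))
  perSlice <- data.frame(slice = slices, count = counts,
                         volume_ml = counts * voxMm3 / 1000)
  new("FatQuantification", perSlice = perSlice,
      totalMl = sum(perSlice$volume_ml), threshold = threshold,
      voxelVolumeMm3 = voxMm3)
}

#' Subsample the per-slice table at a fixed slice interval
#'
#' Keeps slices at positions low, low+step, low+2*step, ... of the
#' analysis range — e.g. every 10th slice of a ~100-slice stack for the
#' observer-variability analysis, spacing the retained slices far enough
#' apart to be treated as independent segmentations.
#'
#' @param perSlice a per-slice data.frame (from
#'   \code{\link{perSliceTable}}) or a
#'   \code{\linkS4class{FatQuantification}}.
#' @param step positive integer slice stride.
#' @return The subsampled per-slice data.frame.
#' @export
subsampleSlices <- function(perSlice, step) {
  if (is(perSlice, "FatQuantification")) perSlice <- perSlice@perSlice
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  lo <- min(perSlice$slice); hi <- max(perSlice$slice)
  keep <- seq(lo, hi, by = step)
  perSlice[perSlice$slice %in% keep, , drop = FALSE]
}
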