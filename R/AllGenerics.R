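#' @include AllClasses.R
NULL

#' Accessors for epifat objects
#'
#' Small accessor generics giving read access to the slots of the core
#' classes without touching \code{@}.
#'
#' @param object an epifat S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spacingMm", function(object) standardGeneric("spacingMm"))
#' @rdname accessors
#' @export
setGeneric("frameTimesMs", function(object) standardGeneric("frameTimesMs"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("waterImage", function(object) standardGeneric("waterImage"))
#' @rdname accessors
#' @export
setGeneric("fatImage", function(object) standardGeneric("fatImage"))
#' @rdname accessors
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setGeneric("ffArray", function(object) standardGeneric("ffArray"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("sliceRange", function(object) standardGeneric("sliceRange"))
#' @rdname accessors
#' @export
setGeneric("perSliceTable", function(object) standardGeneric("perSliceTable"))
#' @rdname accessors
#' @export
setGeneric("totalVolumeMl", function(object) standardGeneric("totalVolumeMl"))
#' @rdname accessors
#' @export
setGeneric("trueVolumeMl", function(object) standardGeneric("trueVolumeMl"))
#' @rdname accessors
#' @export
setGeneric("groundTruthROI", function(object) standardGeneric("groundTruthROI"))

#' Compute a fat-fraction map
#'
#' @param water water image (3D array) or a
#'   \code{\linkS4class{DixonSeries}}.
#' @param ... further arguments passed to methods.
#' @export
setGeneric("fatFraction", function(water, ...) standardGeneric("fatFraction"))

setMethod("spacingMm", "DixonSeries", function(object) object@spacingMm)
setMethod("spacingMm", "TissueLabelMap", function(object) object@spacingMm)
setMethod("spacingMm", "FatFractionMap", function(object) object@spacingMm)
setMethod("frameTimesMs", "DixonSeries", function(object) object@frameTimesMs)
setMethod("nFrames", "DixonSeries", function(object) dim(object@water)[4L])
setMethod("nFrames", "TissueLabelMap", function(object) dim(object@labels)[4L])
setMethod("nFrames", "PhantomSpec", function(object) object@nFrames)
setMethod("waterImage", "DixonSeries", function(object) object@water)
setMethod("fatImage", "DixonSeries", function(object) object@fat)
setMethod("labelArray", "TissueLabelMap", function(object) object@labels)
setMethod("ffArray", "FatFractionMap", function(object) object@ff)
setMethod("roiMask", "EpicardialROISet", function(object) object@mask)
setMethod("sliceRange", "EpicardialROISet", function(object) object@sliceRange)
setMethod("sliceRange", "GroundTruth", function(object) object@sliceRange)
setMethod("perSliceTable", "FatQuantification", function(object) object@perSlice)
setMethod("totalVolumeMl", "FatQuantification", function(object) object@totalMl)
setMethod("trueVolumeMl", "GroundTruth", function(object) object@trueVolumeMl)
setMethod("groundTruthROI", "GroundTruth", function(object) object@roi)

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:",
      paste(object@gridShape, collapse = " x "), "voxels @",
      paste(object@voxelSpacingMm, collapse = " x "), "mm,",
      object@nFrames, "frames /", object@temporalResolutionMs, "ms\n")
  cat("  motion:", object@motionAmplitudeMm, "mm longitudinal, contraction",
      object@contractionFraction, "| noise sd", object@noiseSigma,
      "| seed", object@seed, "\n")
})

setMethod("show", "DixonSeries", function(object) {
  d <- dim(object@water)
  cat("DixonSeries:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4L], "frames @", paste(object@spacingMm, collapse = " x "), "mm\n")
})

setMethod("show", "TissueLabelMap", function(object) {
  d <- dim(object@labels)
  cat("TissueLabelMap:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4L], "frames\n")
})

setMethod("show", "FatFractionMap", function(object) {
  cat("FatFractionMap:", paste(dim(object@ff), collapse = " x "),
      "| FF range", sprintf("[%.3f, %.3f]", min(object@ff), max(object@ff)),
      "| frame time", object@frameTimeMs, "ms\n")
})

setMethod("show", "EpicardialROISet", function(object) {
  cat("EpicardialROISet: slices", object@sliceRange[1L], "-",
      object@sliceRange[2L], "on frame", object@frameIndex, "\n")
})

setMethod("show", "FatQuantification", function(object) {
  cat("FatQuantification:", nrow(object@perSlice), "slices, total",
      sprintf("%.2f ml", object@totalMl),
      "(threshold", object@threshold, ")\n")
})

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("AgreementResult (n = %d pairs)\n", object@nPairs))
  cat(sprintf("  bias %.3f ml, SD %.3f ml, LoA [%.3f, %.3f]\n",
              object@meanDiffMl, object@sdDiffMl,
              object@loaLow, object@loaHigh))
  if (!is.na(object@meanDiffPct))
    cat(sprintf("  bias %.3f %%, SD %.3f %%\n",
                object@meanDiffPct, object@sdDiffPct))
  if (!is.na(object@icc))
    cat(sprintf("  ICC %.3f (%s)\n", object@icc, object@iccCategory))
})
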