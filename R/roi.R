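#' @include AllClasses.R
NULL

#' Construct an EpicardialROISet from per-slice binary masks
#'
#' @param mask 3D logical (or 0/1 numeric) array, \code{TRUE} inside the
#'   outer epicardial boundary.
#' @param sliceRange inclusive 1-based (low, high) analysis z range;
#'   defaults to the range of slices with any ROI coverage.
#' @param frameIndex 1-based cine frame the ROI belongs to.
#' @return An \code{\linkS4class{EpicardialROISet}}.
#' @export
EpicardialROISet <- function(mask, sliceRange = NULL, frameIndex = 1L) {
  mask <- as.array(mask) > 0
  if (length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  if (is.null(sliceRange)) {
    covered <- which(apply(mask, 3L, any))
    if (!length(covered)) stop("ROI mask is empty")
    sliceRange <- range(covered)
  }
  new("EpicardialROISet", mask = mask,
      sliceRange = as.integer(sliceRange), frameIndex = as.integer(frameIndex))
}

# Even-odd (crossing-number) point-in-polygon test; vertices in voxel
# coordinates, points are voxel centres.
.pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize per-slice polygon ROIs to an EpicardialROISet
#'
#' Polygons are simple closed contours in 1-based voxel coordinates
#' (x, y); a voxel belongs to the ROI if its centre is inside the polygon
#' under the even-odd rule.
#'
#' @param polygons named list: names are 1-based slice indices, each
#'   element an n x 2 matrix (or list of [x, y] pairs) of vertices.
#' @param dim integer(3), target volume shape.
#' @param sliceRange optional analysis range; defaults to the polygon
#'   slice extent.
#' @param frameIndex 1-based frame index.
#' @return An \code{\linkS4class{EpicardialROISet}}.
#' @export
polygonROI <- function(polygons, dim, sliceRange = NULL, frameIndex = 1L) {
  dim <- as.integer(dim)
  mask <- array(FALSE, dim = dim)
  px <- rep(seq_len(dim[1L]), times = dim[2L])
  py <- rep(seq_len(dim[2L]), each = dim[1L])
  for (nm in names(polygons)) {
    z <- as.integer(nm)
    if (z < 1L || z > dim[3L])
      stop("polygon slice ", nm, " outside the volume extent")
    poly <- polygons[[nm]]
    if (is.list(poly)) poly <- do.call(rbind, lapply(poly, unlist))
    poly <- as.matrix(poly)
    if (nrow(poly) < 3L) stop("polygon on slice ", nm, " has < 3 vertices")
    mask[, , z] <- matrix(.pointInPolygon(px, py, poly),
                          dim[1L], dim[2L])
  }
  EpicardialROISet(mask, sliceRange = sliceRange, frameIndex = frameIndex)
}

#' Read an ROI from a JSON polygon file or NIfTI label volume
#'
#' JSON layout: \code{{"slices": {"<z>": [[x, y], ...], ...}}} with
#' optional top-level \code{slice_range} and \code{frame_index}; any other
#' file is read as a NIfTI label volume (non-zero = inside).
#'
#' @param path file path.
#' @param dim required for JSON input: target volume shape.
#' @return An \code{\linkS4class{EpicardialROISet}}.
#' @export
readROI <- function(path, dim = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(dim)) stop("dim is required for polygon ROI input")
    polygonROI(obj$slices, dim = dim,
               sliceRange = if (!is.null(obj$slice_range))
                 as.integer(obj$slice_range) else NULL,
               frameIndex = if (!is.null(obj$frame_index))
                 as.integer(obj$frame_index) else 1L)
  } else {
    v <- readVolume(path)
    dat <- v$data
    if (length(dim(dat)) == 4L) dat <- array(dat[, , , 1L], dim(dat)[1:3])
    EpicardialROISet(dat > 0)
  }
}

#' Perturb ROI boundaries to emulate observer re-segmentation
#'
#' Applies, per slice of the analysis range, a morphological dilation or
#' erosion (direction drawn at random) of the ROI with a disc of radius
#' \code{amplitudeVox} — a simple model of the boundary placement
#' variability between human observers, whose per-slice volume error
#' grows with the amplitude. Amplitude 0 returns the ROI unchanged.
#'
#' @param roi an \code{\linkS4class{EpicardialROISet}}.
#' @param amplitudeVox non-negative integer jitter amplitude in voxels.
#' @param seed integer seed.
#' @return A jittered \code{\linkS4class{EpicardialROISet}}.
#' @export
jitterROI <- function(roi, amplitudeVox, seed) {
  amplitudeVox <- as.integer(amplitudeVox)
  if (amplitudeVox < 0) stop("amplitudeVox must be >= 0")
  if (amplitudeVox == 0L) return(roi)
  mask <- roi@mask
  sr <- roi@sliceRange
  withSeed(seed, {
    brush <- EBImage::makeBrush(2L * amplitudeVox + 1L, shape = "disc")
    for (z in sr[1L]:sr[2L]) {
      sl <- mask[, , z] + 0
      sl <- if (sample(c(TRUE, FALSE), 1L)) EBImage::dilate(sl, brush)
            else EBImage::erode(sl, brush)
      mask[, , z] <- sl > 0
    }
  })
  new("EpicardialROISet", mask = mask, sliceRange = sr,
      frameIndex = roi@frameIndex)
}
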