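#' @include AllClasses.R AllGenerics.R
NULL

# Core FF arithmetic shared by the methods.
.computeFF <- function(W, F, eps) {
  if (!identical(dim(W), dim(F)))
    stop("water and fat images must have the same shape")
  nneg <- sum(W < 0) + sum(F < 0)
  if (nneg > 0) {
    message(nneg, " negative input voxels clipped to 0")
    W[W < 0] <- 0
    F[F < 0] <- 0
  }
  if (is.null(eps)) {
    m <- max(max(W), max(F))
    eps <- if (m > 0) 1e-6 * m else .Machine$double.eps
  }
  if (eps <= 0) stop("eps must be positive")
  total <- W + F
  ff <- ifelse(total > eps, F / total, 0)  # signal voids -> FF = 0
  ff[ff < 0] <- 0
  ff[ff > 1] <- 1
  array(ff, dim = if (is.null(dim(W))) length(W) else dim(W))
}

#' @describeIn fatFraction compute FF = F/(F+W) from water and fat arrays.
#'   Voxels whose total signal falls at or below \code{eps} (default
#'   \code{1e-6} of the channel maximum) are set to \code{FF = 0}, the
#'   signal-void convention, so chamber and background voxels fall below
#'   any fat threshold. Values are clamped to [0, 1]. Returns a bare array
#'   when \code{spacingMm} is \code{NULL}, otherwise a
#'   \code{\linkS4class{FatFractionMap}}.
#' @param fat fat image, same shape as \code{water}.
#' @param eps positive scalar; denominator cutoff for the void convention.
#' @param spacingMm voxel spacing in mm (3 values) for the returned map.
#' @param frameTimeMs cardiac phase of the frame (ms).
#' @export
setMethod("fatFraction", "array",
  function(water, fat, eps = NULL, spacingMm = NULL, frameTimeMs = NA_real_) {
    ff <- .computeFF(water, fat, eps)
    if (is.null(spacingMm)) return(ff)
    new("FatFractionMap", ff = ff, spacingMm = as.numeric(spacingMm),
        frameTimeMs = as.numeric(frameTimeMs))
  })

#' @describeIn fatFraction numeric vectors are handled like arrays.
#' @export
setMethod("fatFraction", "numeric",
  function(water, fat, eps = NULL) {
    as.numeric(.computeFF(as.array(water), as.array(fat), eps))
  })

#' @describeIn fatFraction compute the FF map of one cine frame of a
#'   \code{\linkS4class{DixonSeries}}; always returns a
#'   \code{\linkS4class{FatFractionMap}} carrying the frame time.
#' @param frame 1-based cine frame index.
#' @export
setMethod("fatFraction", "DixonSeries",
  function(water, frame = 1L, eps = NULL) {
    series <- water
    nf <- dim(series@water)[4L]
    if (frame < 1L || frame > nf)
      stop("frame index out of range")
    W <- array(series@water[, , , frame], dim(series@water)[1:3])
    F <- array(series@fat[, , , frame], dim(series@fat)[1:3])
    new("FatFractionMap", ff = .computeFF(W, F, eps),
        spacingMm = series@spacingMm,
        frameTimeMs = series@frameTimesMs[frame])
  })
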