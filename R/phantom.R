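#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a phantom specification
#'
#' Builds a \code{\linkS4class{PhantomSpec}} with defaults emulating a
#' contrast-enhanced axial whole-heart cine Dixon acquisition at 1.5 T:
#' acquired voxel 1.5 x 1.5 x 3.0 mm on a 64 x 64 x 40 grid, 15 cine
#' frames at 65 ms temporal resolution over a 1000 ms cardiac cycle.
#' The anatomy is a stylized set of nested ellipsoids: blood pool inside
#' a myocardial shell, wrapped in an epicardial fat rind, a one-voxel
#' pericardium, and a static paracardial fat slab lateral to the heart.
#' Blood-pool water signal is high, emulating contrast enhancement.
#'
#' @param gridShape voxels per axis (x, y, z).
#' @param voxelSpacingMm voxel spacing in mm per axis.
#' @param nFrames cine frames per cardiac cycle.
#' @param rrIntervalMs cardiac cycle length (ms).
#' @param temporalResolutionMs frame spacing (ms); frame times are
#'   \code{(0:(nFrames-1)) * temporalResolutionMs}.
#' @param tissueFF named fat fraction per tissue (see
#'   \code{\link{tissueLabels}}).
#' @param tissueSignal named noiseless total signal per tissue.
#' @param bloodRadiiMm semi-axes of the blood-pool ellipsoid (mm).
#' @param wallThicknessMm,fatThicknessMm,pericardiumThicknessMm shell
#'   thicknesses (mm).
#' @param motionAmplitudeMm peak apical displacement of the cardiac
#'   compartments over the cycle (mm).
#' @param contractionFraction peak in-plane radial contraction, in [0, 0.5).
#' @param noiseSigma additive Gaussian noise SD (signal units).
#' @param fieldmapHz amplitude of the smooth off-resonance map used for
#'   complex-echo synthesis (Hz).
#' @param seed integer seed for all phantom randomness.
#' @return A validated \code{\linkS4class{PhantomSpec}}.
#' @examples
#' spec <- PhantomSpec(nFrames = 4L, gridShape = c(32L, 32L, 20L))
#' spec
#' @export
PhantomSpec <- function(gridShape = c(64L, 64L, 40L),
                        voxelSpacingMm = c(1.5, 1.5, 3.0),
                        nFrames = 15L,
                        rrIntervalMs = 1000,
                        temporalResolutionMs = 65,
                        tissueFF = c(background = 0, lung = 0,
                                     blood_pool = 0.05, myocardium = 0.10,
                                     epicardial_fat = 0.80, pericardium = 0.10,
                                     paracardial_fat = 0.80),
                        tissueSignal = c(background = 0, lung = 0.1,
                                         blood_pool = 1.0, myocardium = 0.6,
                                         epicardial_fat = 1.0,
                                         pericardium = 0.5,
                                         paracardial_fat = 1.0),
                        bloodRadiiMm = c(20, 20, 25),
                        wallThicknessMm = 8,
                        fatThicknessMm = 6,
                        pericardiumThicknessMm = 1.5,
                        motionAmplitudeMm = 10,
                        contractionFraction = 0.1,
                        noiseSigma = 0,
                        fieldmapHz = 0,
                        seed = 1L) {
  new("PhantomSpec",
      gridShape = as.integer(gridShape),
      voxelSpacingMm = as.numeric(voxelSpacingMm),
      nFrames = as.integer(nFrames),
      rrIntervalMs = as.numeric(rrIntervalMs),
      temporalResolutionMs = as.numeric(temporalResolutionMs),
      tissueFF = tissueFF[names(tissueLabels)],
      tissueSignal = tissueSignal[names(tissueLabels)],
      bloodRadiiMm = as.numeric(bloodRadiiMm),
      wallThicknessMm = as.numeric(wallThicknessMm),
      fatThicknessMm = as.numeric(fatThicknessMm),
      pericardiumThicknessMm = as.numeric(pericardiumThicknessMm),
      motionAmplitudeMm = as.numeric(motionAmplitudeMm),
      contractionFraction = as.numeric(contractionFraction),
      noiseSigma = as.numeric(noiseSigma),
      fieldmapHz = as.numeric(fieldmapHz),
      seed = as.integer(seed))
}

#' Per-tissue water and fat signal amplitudes
#'
#' Derived from the total signal and the true fat fraction:
#' \code{W = S * (1 - FF)}, \code{F = S * FF}, so the noiseless phantom
#' satisfies \code{F/(F+W) = FF} exactly wherever \code{S > 0}.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @return Named numeric vector per tissue label.
#' @export
tissueWaterSignal <- function(spec) spec@tissueSignal * (1 - spec@tissueFF)

#' @rdname tissueWaterSignal
#' @export
tissueFatSignal <- function(spec) spec@tissueSignal * spec@tissueFF

# Motion phase s(t) in [0, 1]: sin^2 ramp peaking mid-cycle (systole
# analogue). Frames are 1-based; phase uses the 0-based index.
.motionPhase <- function(frame, nFrames) sin(pi * (frame - 1L) / nFrames)^2

# Shell semi-axes (mm), innermost to outermost.
.shellRadii <- function(spec) {
  r1 <- spec@bloodRadiiMm
  r2 <- r1 + spec@wallThicknessMm
  r3 <- r2 + spec@fatThicknessMm
  r4 <- r3 + spec@pericardiumThicknessMm
  list(blood_pool = r1, myocardium = r2, epicardial_fat = r3,
       pericardium = r4)
}

# Geometry of the static paracardial slab: placed lateral (+x) to the
# heart with a clearance gap so the purely longitudinal cardiac motion can
# never reach it.
.slabGeometry <- function(spec, centre, r4) {
  gap <- 3; thickness <- 8
  list(xlo = centre[1L] + r4[1L] + gap,
       xhi = centre[1L] + r4[1L] + gap + thickness,
       yHalf = r4[2L], zHalf = r4[3L])
}

#' Build the phantom anatomy
#'
#' Rasterizes the nested-ellipsoid anatomy on the phantom grid for every
#' cine frame. Per frame \code{t} (1-based), the cardiac compartments are
#' translated apically by
#' \code{motionAmplitudeMm * sin^2(pi*(t-1)/nFrames)} and contracted
#' in-plane by \code{1 - contractionFraction * sin^2(...)}; the
#' paracardial fat, lung and background are identical in every frame.
#' Deterministic given the spec.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @return A \code{\linkS4class{TissueLabelMap}}.
#' @examples
#' lab <- buildAnatomy(PhantomSpec(nFrames = 2L, gridShape = c(32L, 32L, 20L),
#'                                 bloodRadiiMm = c(8, 8, 10),
#'                                 wallThicknessMm = 3, fatThicknessMm = 2.5,
#'                                 motionAmplitudeMm = 3))
#' table(labelArray(lab)[, , , 1])
#' @export
buildAnatomy <- function(spec) {
  validObject(spec)
  nx <- spec@gridShape[1L]; ny <- spec@gridShape[2L]; nz <- spec@gridShape[3L]
  sp <- spec@voxelSpacingMm
  extent <- spec@gridShape * sp
  centre <- extent / 2
  radii <- .shellRadii(spec)

  # Sizing checks, innermost shell first, so the error names the first
  # shell that does not fit (z allows for the full apical excursion).
  for (shell in names(radii)) {
    r <- radii[[shell]]
    fits <- centre[1L] - r[1L] >= 0 && centre[1L] + r[1L] <= extent[1L] &&
            centre[2L] - r[2L] >= 0 && centre[2L] + r[2L] <= extent[2L] &&
            centre[3L] - r[3L] - spec@motionAmplitudeMm >= 0 &&
            centre[3L] + r[3L] <= extent[3L]
    if (!fits)
      stop("grid too small to contain shell '", shell, "'")
  }
  slab <- .slabGeometry(spec, centre, radii$pericardium)
  if (slab$xhi > extent[1L])
    stop("grid too small to contain shell 'paracardial_fat'")

  # Voxel centre coordinates (mm).
  xc <- (seq_len(nx) - 0.5) * sp[1L]
  yc <- (seq_len(ny) - 0.5) * sp[2L]
  zc <- (seq_len(nz) - 0.5) * sp[3L]

  # Static compartments, shared by all frames.
  thoraxR <- pmax(extent / 2 - 1, 1)
  eThorax <- outer(outer(((xc - centre[1L]) / thoraxR[1L])^2,
                         ((yc - centre[2L]) / thoraxR[2L])^2, "+"),
                   ((zc - centre[3L]) / thoraxR[3L])^2, "+")
  inSlab <- outer(outer(xc >= slab$xlo & xc <= slab$xhi,
                        abs(yc - centre[2L]) <= slab$yHalf, "&"),
                  abs(zc - centre[3L]) <= slab$zHalf, "&")
  static <- array(tissueLabels["background"], dim = c(nx, ny, nz))
  static[eThorax <= 1] <- tissueLabels["lung"]
  static[inSlab] <- tissueLabels["paracardial_fat"]

  labels <- array(NA_integer_, dim = c(nx, ny, nz, spec@nFrames))
  for (t in seq_len(spec@nFrames)) {
    s <- .motionPhase(t, spec@nFrames)
    scale <- 1 - spec@contractionFraction * s
    dz <- spec@motionAmplitudeMm * s       # apical = toward lower z
    qx2 <- ((xc - centre[1L]) / scale)^2
    qy2 <- ((yc - centre[2L]) / scale)^2
    qz2 <- (zc - (centre[3L] - dz))^2
    ell <- function(r) outer(outer(qx2 / r[1L]^2, qy2 / r[2L]^2, "+"),
                             qz2 / r[3L]^2, "+")
    frame <- static
    frame[ell(radii$pericardium) <= 1]   <- tissueLabels["pericardium"]
    frame[ell(radii$epicardial_fat) <= 1] <- tissueLabels["epicardial_fat"]
    frame[ell(radii$myocardium) <= 1]    <- tissueLabels["myocardium"]
    frame[ell(radii$blood_pool) <= 1]    <- tissueLabels["blood_pool"]
    labels[, , , t] <- frame
  }
  new("TissueLabelMap", labels = labels, spacingMm = sp)
}

#' Render water/fat images and ground truth from the anatomy
#'
#' Assigns each voxel its tissue's noiseless water and fat amplitudes
#' (\code{\link{tissueWaterSignal}}), adds zero-mean Gaussian noise with
#' SD \code{noiseSigma} independently per channel and frame (seeded from
#' \code{spec@seed}), and clips at zero. The ground truth carries the
#' epicardial fat mask, its per-frame volume, a per-frame ROI (the filled
#' region inside the outer epicardial fat boundary, i.e. blood pool +
#' myocardium + epicardial fat), each frame's fat slice range, and the
#' union analysis slice range.
#'
#' @param labels a \code{\linkS4class{TissueLabelMap}} from
#'   \code{\link{buildAnatomy}}.
#' @param spec the same \code{\linkS4class{PhantomSpec}}.
#' @return A list with elements \code{series}
#'   (\code{\linkS4class{DixonSeries}}) and \code{truth}
#'   (\code{\linkS4class{GroundTruth}}).
#' @export
renderDixon <- function(labels, spec) {
  validObject(labels); validObject(spec)
  lab <- labels@labels
  if (!identical(dim(lab)[1:3], spec@gridShape) ||
      dim(lab)[4L] != spec@nFrames)
    stop("label map shape does not match the phantom spec")
  wLut <- tissueWaterSignal(spec)[names(tissueLabels)]
  fLut <- tissueFatSignal(spec)[names(tissueLabels)]
  idx <- lab + 1L  # labels are 0-based codes
  W <- array(wLut[idx], dim = dim(lab))
  F <- array(fLut[idx], dim = dim(lab))
  if (spec@noiseSigma > 0) {
    withSeed(spec@seed, {
      W <- W + array(stats::rnorm(length(W), 0, spec@noiseSigma), dim(W))
      F <- F + array(stats::rnorm(length(F), 0, spec@noiseSigma), dim(F))
    })
    W[W < 0] <- 0
    F[F < 0] <- 0
  }
  times <- (seq_len(spec@nFrames) - 1L) * spec@temporalResolutionMs
  series <- new("DixonSeries", water = W, fat = F,
                spacingMm = spec@voxelSpacingMm, frameTimesMs = times)

  voxMl <- prod(spec@voxelSpacingMm) / 1000
  fatMask <- lab == tissueLabels["epicardial_fat"]
  vols <- apply(fatMask, 4L, sum) * voxMl
  rois <- vector("list", spec@nFrames)
  lo <- dim(lab)[3L]; hi <- 1L
  for (t in seq_len(spec@nFrames)) {
    inner <- lab[, , , t] %in% tissueLabels[c("blood_pool", "myocardium",
                                              "epicardial_fat")]
    inner <- array(inner, dim = dim(lab)[1:3])
    fatSlices <- which(apply(fatMask[, , , t, drop = FALSE], 3L, any))
    if (!length(fatSlices))
      stop("frame ", t, " contains no epicardial fat")
    sr <- range(fatSlices)
    lo <- min(lo, sr[1L]); hi <- max(hi, sr[2L])
    rois[[t]] <- new("EpicardialROISet", mask = inner,
                     sliceRange = as.integer(sr), frameIndex = t)
  }
  truth <- new("GroundTruth", fatMask = fatMask, trueVolumeMl = vols,
               roi = rois, sliceRange = as.integer(c(lo, hi)))
  list(series = series, truth = truth)
}

#' Smooth off-resonance field map of the phantom
#'
#' A spatially smooth in-plane sinusoidal map scaled to
#' \code{spec@fieldmapHz} at its peak, constant along z and time. Used by
#' \code{\link{synthesizeEchoes}} and available to
#' \code{\link{dixonSeparate}} as the true field map.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @return 3D numeric array (Hz).
#' @export
phantomFieldMap <- function(spec) {
  nx <- spec@gridShape[1L]; ny <- spec@gridShape[2L]; nz <- spec@gridShape[3L]
  plane <- outer(sin(pi * (seq_len(nx) - 0.5) / nx),
                 sin(pi * (seq_len(ny) - 0.5) / ny))
  array(rep(spec@fieldmapHz * plane, nz), dim = c(nx, ny, nz))
}

#' Synthesize two-point gradient-echo signals from water/fat images
#'
#' Forward signal model
#' \deqn{S(TE) = (W + F e^{i\theta(TE)}) e^{i 2\pi \psi TE / 1000},}
#' with \eqn{\theta(TE) = 2\pi \Delta f_{fw} TE / 1000}, where
#' \eqn{\Delta f_{fw}} is the water-fat shift (default -220 Hz at 1.5 T)
#' and \eqn{\psi} the per-voxel off-resonance map
#' (\code{\link{phantomFieldMap}}; zero when \code{spec@fieldmapHz == 0}).
#'
#' @param series a \code{\linkS4class{DixonSeries}}.
#' @param spec the \code{\linkS4class{PhantomSpec}} (for the field map).
#' @param te1Ms,te2Ms echo times in ms (defaults 2.3 and 3.9).
#' @param deltaFHz water-fat frequency shift in Hz.
#' @return An \code{\linkS4class{EchoPair}} with 4D complex volumes.
#' @export
synthesizeEchoes <- function(series, spec, te1Ms = 2.3, te2Ms = 3.9,
                             deltaFHz = -220) {
  if (te1Ms <= 0 || te2Ms <= 0)
    stop("echo times must be positive")
  if (te2Ms <= te1Ms)
    stop("te2Ms must exceed te1Ms")
  W <- series@water; F <- series@fat
  psi <- phantomFieldMap(spec)
  if (!identical(dim(psi), dim(W)[1:3]))
    stop("field map shape does not match the series")
  psi4 <- array(rep(psi, dim(W)[4L]), dim = dim(W))
  echo <- function(te) {
    theta <- 2 * pi * deltaFHz * te / 1000
    (W + F * exp(1i * theta)) * exp(1i * 2 * pi * psi4 * te / 1000)
  }
  new("EchoPair", s1 = echo(te1Ms), s2 = echo(te2Ms),
      te1Ms = te1Ms, te2Ms = te2Ms, deltaFHz = deltaFHz)
}

#' Export a phantom dataset to NIfTI + JSON sidecar
#'
#' Writes 4D water and fat volumes, the 4D epicardial fat ground-truth
#' mask, per-frame ROI masks, and a JSON sidecar holding frame times,
#' voxel spacing, seed, the spec parameters and true per-frame volumes.
#' Round-trips losslessly through \code{\link{readVolume}}.
#'
#' @param series a \code{\linkS4class{DixonSeries}}.
#' @param truth the matching \code{\linkS4class{GroundTruth}}.
#' @param path output directory (created if absent).
#' @param spec the generating \code{\linkS4class{PhantomSpec}} (recorded
#'   in the sidecar).
#' @return Invisibly, the sidecar path.
#' @export
exportDataset <- function(series, truth, path, spec = NULL) {
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", path)
  sp <- series@spacingMm
  writeVolume(series@water, sp, file.path(path, "water.nii.gz"))
  writeVolume(series@fat, sp, file.path(path, "fat.nii.gz"))
  writeVolume(truth@fatMask + 0, sp, file.path(path, "fat_mask.nii.gz"))
  roiArr <- array(0, dim = dim(truth@fatMask))
  for (t in seq_along(truth@roi)) roiArr[, , , t] <- truth@roi[[t]]@mask + 0
  writeVolume(roiArr, sp, file.path(path, "roi.nii.gz"))
  side <- list(
    frame_times_ms = series@frameTimesMs,
    voxel_spacing_mm = sp,
    true_volume_ml = truth@trueVolumeMl,
    slice_range = truth@sliceRange,
    roi_slice_ranges = lapply(truth@roi, function(r) r@sliceRange)
  )
  if (!is.null(spec)) {
    side$seed <- spec@seed
    side$spec <- list(
      grid_shape = spec@gridShape, voxel_spacing_mm = spec@voxelSpacingMm,
      n_frames = spec@nFrames, rr_interval_ms = spec@rrIntervalMs,
      temporal_resolution_ms = spec@temporalResolutionMs,
      tissue_ff = as.list(spec@tissueFF),
      tissue_signal = as.list(spec@tissueSignal),
      blood_radii_mm = spec@bloodRadiiMm,
      wall_thickness_mm = spec@wallThicknessMm,
      fat_thickness_mm = spec@fatThicknessMm,
      pericardium_thickness_mm = spec@pericardiumThicknessMm,
      motion_amplitude_mm = spec@motionAmplitudeMm,
      contraction_fraction = spec@contractionFraction,
      noise_sigma = spec@noiseSigma, fieldmap_hz = spec@fieldmapHz)
  }
  sidePath <- file.path(path, "sidecar.json")
  jsonlite::write_json(side, sidePath, auto_unbox = TRUE, digits = NA)
  invisible(sidePath)
}

#' Import a phantom dataset written by exportDataset
#'
#' @param path dataset directory.
#' @return A list with \code{series}, \code{fatMask}, \code{roi} (list of
#'   \code{\linkS4class{EpicardialROISet}}), \code{sliceRange},
#'   \code{trueVolumeMl} and the parsed \code{sidecar}.
#' @export
importDataset <- function(path) {
  sidePath <- file.path(path, "sidecar.json")
  if (!file.exists(sidePath)) stop("no sidecar.json under ", path)
  side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
  w <- readVolume(file.path(path, "water.nii.gz"))
  f <- readVolume(file.path(path, "fat.nii.gz"))
  series <- new("DixonSeries", water = w$data, fat = f$data,
                spacingMm = w$spacingMm,
                frameTimesMs = as.numeric(side$frame_times_ms))
  mask <- readVolume(file.path(path, "fat_mask.nii.gz"))$data > 0.5
  roiArr <- readVolume(file.path(path, "roi.nii.gz"))$data > 0.5
  rsr <- side$roi_slice_ranges
  rois <- lapply(seq_len(dim(roiArr)[4L]), function(t) {
    sr <- if (is.matrix(rsr)) rsr[t, ] else unlist(rsr[[t]])
    new("EpicardialROISet", mask = array(roiArr[, , , t], dim(roiArr)[1:3]),
        sliceRange = as.integer(sr), frameIndex = t)
  })
  list(series = series, fatMask = mask, roi = rois,
       sliceRange = as.integer(side$slice_range),
       trueVolumeMl = as.numeric(side$true_volume_ml), sidecar = side)
}
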