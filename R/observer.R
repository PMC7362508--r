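#' @include phantom.R quantify.R stats.R
NULL

# A compact single-frame phantom cohort on a ~100-slice reconstructed-grid
# stack (1.5 mm slices), heart size varying across patients.
.observerPhantomSpec <- function(scale, seed) {
  PhantomSpec(gridShape = c(64L, 64L, 110L),
              voxelSpacingMm = c(1.5, 1.5, 1.5),
              nFrames = 1L,
              bloodRadiiMm = c(16, 16, 55) * scale,
              wallThicknessMm = 6, fatThicknessMm = 5,
              pericardiumThicknessMm = 1.5,
              motionAmplitudeMm = 0, contractionFraction = 0,
              noiseSigma = 0, seed = seed)
}

#' Simulate an observer-variability segmentation study on phantoms
#'
#' Builds a cohort of noiseless single-frame phantoms with heart sizes
#' varying across "patients", derives each patient's ground-truth
#' epicardial ROI, and emulates two independent observers by perturbing
#' the ROI boundary with \code{\link{jitterROI}} at the given amplitude
#' (amplitude 0 means both observers reproduce the reference ROI
#' exactly). Each observer's segmentation is quantified per slice at the
#' given FF threshold, and every \code{step}-th slice of the analysis
#' range enters the returned table.
#'
#' @param jitterVox ROI boundary jitter amplitude in voxels (>= 0).
#' @param nPatients number of phantom patients.
#' @param step slice stride for the analysis table (default 10).
#' @param threshold FF classification cutoff.
#' @param seed integer seed governing phantom sizes and both observers'
#'   jitter draws.
#' @return data.frame with columns \code{patient}, \code{slice},
#'   \code{obs1_ml}, \code{obs2_ml}.
#' @export
simulateObserverStudy <- function(jitterVox, nPatients = 5L, step = 10L,
                                  threshold = 0.35, seed = 1L) {
  scales <- seq(0.85, 1.15, length.out = nPatients)
  seeds <- childSeeds(seed, 3L * nPatients)
  rows <- vector("list", nPatients)
  for (p in seq_len(nPatients)) {
    spec <- .observerPhantomSpec(scales[p], seeds[3L * p - 2L])
    rd <- renderDixon(buildAnatomy(spec), spec)
    ffm <- fatFraction(rd$series, frame = 1L)
    roi <- rd$truth@roi[[1L]]
    quantObs <- function(jseed) {
      r <- jitterROI(roi, jitterVox, jseed)
      q <- quantifyVolume(classifyFat(ffm, r, threshold),
                          spacingMm = spec@voxelSpacingMm,
                          sliceRange = r@sliceRange, threshold = threshold)
      subsampleSlices(q, step)
    }
    q1 <- quantObs(seeds[3L * p - 1L])
    q2 <- quantObs(seeds[3L * p])
    common <- intersect(q1$slice, q2$slice)
    rows[[p]] <- data.frame(
      patient = sprintf("P%02d", p),
      slice = common,
      obs1_ml = q1$volume_ml[match(common, q1$slice)],
      obs2_ml = q2$volume_ml[match(common, q2$slice)])
  }
  do.call(rbind, rows)
}

#' ICC across jitter amplitudes of the simulated observer study
#'
#' Runs \code{\link{simulateObserverStudy}} at each jitter amplitude and
#' returns the ICC of the two observers' per-slice volume tables — the
#' phantom analogue of the inter-observer agreement analysis. Larger
#' boundary jitter adds measurement variance, so the ICC is expected to
#' fall as the amplitude grows, reaching exactly 1 at amplitude 0.
#'
#' @param jitterVox vector of jitter amplitudes (voxels).
#' @param ... passed to \code{\link{simulateObserverStudy}}.
#' @param iccModel passed to \code{\link{icc}}.
#' @return data.frame with columns \code{jitter_vox}, \code{icc},
#'   \code{n_pairs}.
#' @export
observerStudyICC <- function(jitterVox = 0:3, ..., iccModel = "ICC2") {
  res <- lapply(jitterVox, function(j) {
    tb <- simulateObserverStudy(j, ...)
    data.frame(jitter_vox = j,
               icc = icc(tb$obs1_ml, tb$obs2_ml, model = iccModel),
               n_pairs = nrow(tb))
  })
  do.call(rbind, res)
}
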