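test_that("frame selection picks the nearest frame time", {
  times <- seq(0, 910, by = 65)
  expect_identical(selectFrame(times, 0), 1L)
  # TD = 730 ms: frame at 715 ms is nearest (exhaustive check)
  expect_identical(selectFrame(times, 730), which.min(abs(times - 730)))
  expect_identical(selectFrame(times, 730), 12L)
  expect_identical(selectFrame(c(0, 100), 50), 1L)  # tie -> earlier
  expect_error(selectFrame(numeric(0), 10), "non-empty")
  expect_error(selectFrame(c(0, 0, 10), 5), "increasing")
  expect_error(selectFrame(times, -5), ">= 0")
})

test_that("classification is strict at the threshold", {
  ff <- array(0.35, c(5, 5, 3))
  roi <- EpicardialROISet(array(TRUE, c(5, 5, 3)))
  expect_equal(sum(classifyFat(ff, roi, 0.35)), 0)  # boundary excluded
  ff[1, 1, 2] <- 0.35 + 1e-9
  expect_equal(sum(classifyFat(ff, roi, 0.35)), 1)
})

test_that("classification counts match an exhaustive voxel scan", {
  vals <- c(0.1, 0.3, 0.4, 0.6, 0.9)
  ff <- array(rep(vals, length.out = 75), c(5, 5, 3))
  roi <- EpicardialROISet(array(TRUE, c(5, 5, 3)))
  mask <- classifyFat(ff, roi, 0.35)
  brute <- sum(vapply(seq_along(ff), function(i) ff[i] > 0.35, logical(1)))
  expect_equal(sum(mask), brute)

  # an ROI covering k voxels of FF 0.5 yields exactly k
  roi2mask <- array(FALSE, c(5, 5, 3)); roi2mask[2:4, 2:4, 2] <- TRUE
  ff2 <- array(0, c(5, 5, 3)); ff2[roi2mask] <- 0.5
  mask2 <- classifyFat(ff2, EpicardialROISet(roi2mask), 0.35)
  expect_equal(sum(mask2), 9)

  # voxels outside the analysis slice range never count
  roi3 <- EpicardialROISet(array(TRUE, c(5, 5, 3)), sliceRange = c(2L, 2L))
  expect_equal(sum(classifyFat(array(0.9, c(5, 5, 3)), roi3)), 25)
})

test_that("classification validates threshold, shape and slice extent", {
  ff <- array(0.5, c(4, 4, 4))
  roi <- EpicardialROISet(array(TRUE, c(4, 4, 4)))
  expect_error(classifyFat(ff, roi, 0), "between 0 and 1")
  expect_error(classifyFat(ff, roi, 1), "between 0 and 1")
  expect_error(classifyFat(array(0.5, c(4, 4, 5)), roi), "differ")
})

test_that("volume integration converts counts on the reconstructed grid", {
  m <- array(TRUE, c(10, 10, 10))   # 1000 voxels
  q <- quantifyVolume(m, c(0.8, 0.8, 1.5))
  expect_equal(totalVolumeMl(q), 0.96)
  expect_equal(sum(perSliceTable(q)$count), 1000)

  q0 <- quantifyVolume(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(totalVolumeMl(q0), 0)
  expect_true(all(perSliceTable(q0)$volume_ml == 0))

  # total integrates the analysis range only
  qr <- quantifyVolume(m, c(1, 1, 1), sliceRange = c(3L, 5L))
  expect_equal(totalVolumeMl(qr), 3 * 100 / 1000)
  expect_equal(perSliceTable(qr)$slice, 3:5)
})

test_that("noiseless phantom volume is recovered exactly", {
  ph <- defaultPhantomCache()
  frame <- selectFrame(frameTimesMs(ph$data$series), 730)
  ffm <- fatFraction(ph$data$series, frame = frame)
  roi <- groundTruthROI(ph$data$truth)[[frame]]
  q <- quantifyVolume(classifyFat(ffm, roi, 0.35),
                      spacingMm(ph$data$series), sliceRange(roi), 0.35)
  expect_equal(totalVolumeMl(q), trueVolumeMl(ph$data$truth)[frame])
})

test_that("slice subsampling keeps every step-th slice of the range", {
  ps <- data.frame(slice = 1:100, count = 1:100, volume_ml = (1:100) / 100)
  expect_equal(nrow(subsampleSlices(ps, 10)), 10)
  expect_identical(subsampleSlices(ps, 1), ps)
  ps25 <- data.frame(slice = 1:25, count = 0L, volume_ml = 0)
  expect_equal(subsampleSlices(ps25, 10)$slice, c(1L, 11L, 21L))
  expect_error(subsampleSlices(ps, 0), ">= 1")
})

test_that("total volume is monotone in threshold and ROI size", {
  set.seed(99)
  for (i in 1:10) {
    ff <- array(runif(16 * 16 * 6), c(16, 16, 6))
    roiSmall <- array(FALSE, c(16, 16, 6)); roiSmall[5:10, 5:10, ] <- TRUE
    roiBig <- array(FALSE, c(16, 16, 6)); roiBig[3:14, 3:14, ] <- TRUE
    rs <- EpicardialROISet(roiSmall); rb <- EpicardialROISet(roiBig)
    vol <- function(roi, thr)
      totalVolumeMl(quantifyVolume(classifyFat(ff, roi, thr), c(1, 1, 1)))
    thresholds <- sort(runif(4, 0.05, 0.95))
    vols <- vapply(thresholds, vol, numeric(1), roi = rs)
    expect_true(all(diff(vols) <= 1e-12))        # non-increasing in threshold
    expect_gte(vol(rb, 0.35), vol(rs, 0.35))     # ROI monotonicity
  }
})

test_that("phantom recovery stays within 2% under 2% channel noise", {
  errs <- vapply(1:5, function(s) {
    ph <- toyPhantom(noiseSigma = 0.02, seed = s)
    ffm <- fatFraction(ph$data$series, frame = 1L)
    roi <- groundTruthROI(ph$data$truth)[[1]]
    q <- quantifyVolume(classifyFat(ffm, roi, 0.35),
                        spacingMm(ph$data$series), sliceRange(roi))
    abs(totalVolumeMl(q) - trueVolumeMl(ph$data$truth)[1]) /
      trueVolumeMl(ph$data$truth)[1]
  }, numeric(1))
  expect_true(all(errs < 0.02))
})
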