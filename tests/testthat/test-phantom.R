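test_that("zero motion and contraction give identical frames", {
  lab <- buildAnatomy(toySpec(motionAmplitudeMm = 0, contractionFraction = 0))
  arr <- labelArray(lab)
  for (t in 2:dim(arr)[4]) {
    expect_identical(arr[, , , t], arr[, , , 1])
  }
})

test_that("sin^2 motion returns near baseline at the end of the cycle", {
  # sin^2(0) = 0 and sin^2(pi*(n-1)/n) is small, so frame 1 and the last
  # frame differ by at most a thin boundary layer of cardiac voxels
  lab <- buildAnatomy(toySpec(nFrames = 15L, contractionFraction = 0))
  arr <- labelArray(lab)
  nDiff <- sum(arr[, , , 1] != arr[, , , 15])
  cardiac1 <- sum(arr[, , , 1] %in% tissueLabels[c("blood_pool", "myocardium",
                                                   "epicardial_fat",
                                                   "pericardium")])
  expect_lt(nDiff / cardiac1, 0.25)
})

test_that("epicardial fat rind volume matches the analytic ellipsoid shell", {
  spec <- PhantomSpec()
  lab <- buildAnatomy(spec)
  r2 <- spec@bloodRadiiMm + spec@wallThicknessMm
  r3 <- r2 + spec@fatThicknessMm
  shellMm3 <- 4 * pi / 3 * (prod(r3) - prod(r2))
  count <- sum(labelArray(lab)[, , , 1] == tissueLabels["epicardial_fat"])
  expect_lt(abs(count - shellMm3 / prod(spec@voxelSpacingMm)) /
            (shellMm3 / prod(spec@voxelSpacingMm)), 0.05)
})

test_that("anatomy errors name the first shell that does not fit", {
  expect_error(buildAnatomy(toySpec(bloodRadiiMm = c(100, 8, 10))),
               "blood_pool")
  expect_error(buildAnatomy(toySpec(gridShape = c(32L, 32L, 8L))),
               "blood_pool")
  # blood fits but the wall does not
  expect_error(buildAnatomy(toySpec(bloodRadiiMm = c(26, 8, 10),
                                    wallThicknessMm = 5)),
               "myocardium")
})

test_that("noiseless rendering reproduces tissue fat fractions exactly", {
  ph <- toyPhantom(noiseSigma = 0)
  lab <- labelArray(buildAnatomy(ph$spec))
  W <- waterImage(ph$data$series); Fa <- fatImage(ph$data$series)
  fatVox <- lab == tissueLabels["epicardial_fat"]
  ff <- Fa[fatVox] / (Fa[fatVox] + W[fatVox])
  expect_equal(unique(ff), ph$spec@tissueFF[["epicardial_fat"]])
  myoVox <- lab == tissueLabels["myocardium"]
  ffMyo <- Fa[myoVox] / (Fa[myoVox] + W[myoVox])
  expect_equal(unique(ffMyo), ph$spec@tissueFF[["myocardium"]],
               tolerance = 1e-12)
})

test_that("rendering is bit-identical for the same spec and seed", {
  a <- toyPhantom(noiseSigma = 0.05)
  b <- toyPhantom(noiseSigma = 0.05)
  expect_identical(waterImage(a$data$series), waterImage(b$data$series))
  expect_identical(fatImage(a$data$series), fatImage(b$data$series))
})

test_that("distinct seeds change the noise but not the labels", {
  a <- buildAnatomy(toySpec(seed = 1L))
  b <- buildAnatomy(toySpec(seed = 2L))
  expect_identical(labelArray(a), labelArray(b))
  ra <- renderDixon(a, toySpec(seed = 1L, noiseSigma = 0.05))
  rb <- renderDixon(b, toySpec(seed = 2L, noiseSigma = 0.05))
  expect_false(identical(waterImage(ra$series), waterImage(rb$series)))
})

test_that("empirical FF over the fat rind stays near truth under noise", {
  # Monte Carlo over 10 seeds at 5% noise on the default geometry
  spec0 <- PhantomSpec()
  lab <- buildAnatomy(spec0)
  fatVox <- labelArray(lab)[, , , 1] == tissueLabels["epicardial_fat"]
  means <- vapply(1:10, function(s) {
    spec <- PhantomSpec(noiseSigma = 0.05, seed = s)
    rd <- renderDixon(lab, spec)
    ffm <- fatFraction(rd$series, frame = 1L)
    mean(ffArray(ffm)[fatVox])
  }, numeric(1))
  expect_true(all(abs(means - 0.80) < 0.02))
})

test_that("paracardial fat is static while the fat rind moves with the heart", {
  spec <- toySpec(nFrames = 6L, motionAmplitudeMm = 4,
                  contractionFraction = 0)
  arr <- labelArray(buildAnatomy(spec))
  para <- arr == tissueLabels["paracardial_fat"]
  for (t in 2:6) expect_identical(para[, , , t], para[, , , 1])
  # longitudinal centroid excursion ~ motion amplitude (within 20%)
  cz <- vapply(1:6, function(t) {
    m <- arr[, , , t] == tissueLabels["epicardial_fat"]
    mean((which(m, arr.ind = TRUE)[, 3] - 0.5) * spec@voxelSpacingMm[3])
  }, numeric(1))
  peak <- max(sin(pi * (0:5) / 6)^2)
  expect_lt(abs(diff(range(cz)) - spec@motionAmplitudeMm * peak),
            0.2 * spec@motionAmplitudeMm)
})

test_that("true fat volume is conserved across frames under pure translation", {
  ph <- toyPhantom(contractionFraction = 0, motionAmplitudeMm = 4)
  vols <- trueVolumeMl(ph$data$truth)
  # one boundary-voxel layer ~ rind surface * one voxel; allow 10%
  expect_lt(diff(range(vols)) / mean(vols), 0.10)
})

test_that("ground-truth ROI encloses the fat mask on every analysis slice", {
  ph <- toyPhantom()
  truth <- ph$data$truth
  for (t in seq_along(groundTruthROI(truth))) {
    roi <- groundTruthROI(truth)[[t]]
    fat <- truth@fatMask[, , , t]
    sr <- sliceRange(roi)
    for (z in sr[1]:sr[2]) {
      expect_true(all(roiMask(roi)[, , z][fat[, , z]]))
    }
    vol <- sum(fat) * prod(spacingMm(ph$data$series)) / 1000
    expect_equal(vol, trueVolumeMl(truth)[t])
  }
})

test_that("synthesized echoes follow the two-point phasor model", {
  # water-only voxels: |S| = W at both echoes
  ph <- toyPhantom(tissueFF = c(background = 0, lung = 0, blood_pool = 0,
                                myocardium = 0, epicardial_fat = 0,
                                pericardium = 0, paracardial_fat = 0))
  pair <- synthesizeEchoes(ph$data$series, ph$spec)
  expect_equal(Mod(pair@s1), waterImage(ph$data$series), tolerance = 1e-12)
  expect_equal(Mod(pair@s2), waterImage(ph$data$series), tolerance = 1e-12)

  # opposed phase: W = 1, F = 0.5 gives S = 0.5 + 0i
  df <- -220
  teOP <- 1000 / (2 * abs(df))   # theta = -pi
  thetaOP <- fatPhasorAngle(teOP, df)
  expect_equal(1 + 0.5 * exp(1i * thetaOP), 0.5 + 0i, tolerance = 1e-12)

  # phasor angles at the protocol echo times, against hand arithmetic
  expect_equal(fatPhasorAngle(2.3, -220), 2 * pi * -220 * 2.3 / 1000)
  expect_equal(fatPhasorAngle(3.9, -220), 2 * pi * -220 * 3.9 / 1000)

  expect_error(synthesizeEchoes(ph$data$series, ph$spec, te1Ms = -1),
               "positive")
  expect_error(synthesizeEchoes(ph$data$series, ph$spec,
                                te1Ms = 3.9, te2Ms = 2.3), "exceed")
})

test_that("datasets round-trip through export and import", {
  ph <- toyPhantom(nFrames = 4L)
  dir <- withr::local_tempdir()
  exportDataset(ph$data$series, ph$data$truth, dir, spec = ph$spec)
  back <- importDataset(dir)
  expect_equal(waterImage(back$series), waterImage(ph$data$series))
  expect_equal(fatImage(back$series), fatImage(ph$data$series))
  expect_equal(spacingMm(back$series), spacingMm(ph$data$series))
  expect_identical(back$fatMask, ph$data$truth@fatMask)
  expect_equal(back$trueVolumeMl, trueVolumeMl(ph$data$truth))
  expect_length(back$sidecar$frame_times_ms, 4L)
})

test_that("sidecar frame times follow the temporal resolution", {
  ph <- toyPhantom(nFrames = 15L, temporalResolutionMs = 65)
  expect_equal(frameTimesMs(ph$data$series), seq(0, 910, by = 65))
})
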