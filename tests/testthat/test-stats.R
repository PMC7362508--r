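test_that("Bland-Altman matches hand-computed closed forms", {
  r <- blandAltman(c(1, 2, 3, 4), c(1, 1, 4, 4))
  d <- c(0, 1, -1, 0)
  expect_equal(r@meanDiffMl, 0)
  expect_equal(r@sdDiffMl, sqrt(sum((d - mean(d))^2) / 3))
  expect_equal(r@loaLow, -1.96 * r@sdDiffMl)
  expect_equal(r@loaHigh, 1.96 * r@sdDiffMl)
  expect_equal(r@nPairs, 4L)

  same <- blandAltman(c(2, 3), c(2, 3))
  expect_equal(same@meanDiffMl, 0)
  expect_equal(same@sdDiffMl, 0)

  off <- blandAltman(c(5, 6, 7), c(2, 3, 4))  # y = x - 3
  expect_equal(off@meanDiffMl, 3)
  expect_equal(off@sdDiffMl, 0)
  expect_equal(c(off@loaLow, off@loaHigh), c(3, 3))

  expect_error(blandAltman(1:3, 1:4), "equal length")
  expect_error(blandAltman(1, 1), "at least 2")
})

test_that("Bland-Altman bias is antisymmetric with invariant spread", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    a <- blandAltman(x, y); b <- blandAltman(y, x)
    expect_equal(a@meanDiffMl, -b@meanDiffMl)
    expect_equal(a@sdDiffMl, b@sdDiffMl)
  }
})

test_that("percent errors divide by the patient total", {
  expect_equal(percentError(0.39, "p1", c(p1 = 165)), 0.39 / 165 * 100)
  expect_equal(percentError(0, "p1", c(p1 = 10)), 0)
  expect_equal(percentError(1, "p1", c(p1 = 100)), 1)
  expect_equal(percentError(c(1, 2), c("a", "b"), c(a = 100, b = 50)),
               c(1, 4))
  expect_error(percentError(1, "a", c(a = 0)), "positive")
  expect_error(percentError(1, "zz", c(a = 10)), "zz")
})

test_that("ICC(2,1) agrees with an independent mean-squares oracle", {
  set.seed(3)
  tables <- list(
    list(x = c(9, 6, 8, 7, 10, 6), y = c(2, 1, 4, 1, 5, 2)),
    list(x = c(1, 2, 3, 4, 5, 6), y = c(1.1, 2.2, 2.9, 4.3, 4.8, 6.1)),
    list(x = c(10, 20, 15, 30, 25, 40), y = c(12, 18, 16, 28, 27, 38)),
    list(x = rnorm(12), y = rnorm(12))
  )
  for (tb in tables) {
    expect_equal(icc(tb$x, tb$y), iccOracle(tb$x, tb$y), tolerance = 1e-10)
  }
})

test_that("ICC hits its reference points and conventions", {
  x <- c(1, 5, 3, 9, 7)
  expect_equal(icc(x, x), 1)                    # perfect agreement
  set.seed(17)
  a <- rnorm(200); b <- rnorm(200)              # no subject effect at all
  expect_lt(abs(icc(a, b)), 0.2)
  expect_warning(v <- icc(rep(2, 5), rep(2, 5)), "convention")
  expect_equal(v, 1)
  expect_error(icc(1:2, 1:2), "at least 3")
  expect_error(icc(c(1, NA, 3), c(1, 2, 3)), "missing")
})

test_that("ICC is invariant under common shift and positive scaling", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(15, 10, 3); y <- x + rnorm(15, 0, 1)
    base <- icc(x, y)
    expect_equal(icc(x + 7, y + 7), base, tolerance = 1e-10)
    expect_equal(icc(3 * x, 3 * y), base, tolerance = 1e-10)
  }
})

test_that("ICC categories follow the 0.5/0.75/0.9 convention", {
  expect_equal(interpretICC(0.96), "excellent")
  expect_equal(interpretICC(0.92), "excellent")
  expect_equal(interpretICC(0.76), "good")
  expect_equal(interpretICC(0.63), "moderate")
  expect_equal(interpretICC(0.2), "poor")
  # boundaries belong to the upper class
  expect_equal(interpretICC(0.5), "moderate")
  expect_equal(interpretICC(0.75), "good")
  expect_equal(interpretICC(0.9), "excellent")
  expect_error(interpretICC(1.5), "\\[-1, 1\\]")
})

test_that("body surface area follows the Mosteller closed form", {
  expect_equal(bodySurfaceArea(180, 72), sqrt(3.6))
  expect_equal(bodySurfaceArea(180, 20), 1.0)
  expect_equal(bodySurfaceArea(160, 90), 2.0)
  expect_equal(bodySurfaceArea(180, 72, "dubois"),
               0.007184 * 180^0.725 * 72^0.425)
  expect_error(bodySurfaceArea(-1, 70), "positive")
})

test_that("BMI regression matches closed-form OLS", {
  bmi <- c(22, 24, 27, 30, 35)
  y <- c(40, 55, 60, 80, 95)
  fit <- regressBMI(y, bmi)
  # closed forms
  slope <- sum((bmi - mean(bmi)) * (y - mean(y))) / sum((bmi - mean(bmi))^2)
  intercept <- mean(y) - slope * mean(bmi)
  yhat <- intercept + slope * bmi
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  se <- sqrt(sum((y - yhat)^2) / 3 / sum((bmi - mean(bmi))^2))
  p <- 2 * stats::pt(abs(slope / se), df = 3, lower.tail = FALSE)
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
  expect_equal(fit$p_value, p, tolerance = 1e-10)

  exact <- regressBMI(2 * bmi, bmi)
  expect_equal(exact$slope, 2)
  expect_equal(exact$r_squared, 1)
  expect_equal(regressBMI(rep(5, 5), bmi)$r_squared, 0)
  expect_error(regressBMI(y, rep(25, 5)), "constant")
})

test_that("paired comparisons separate shifted data and handle identity", {
  set.seed(12)
  a <- rnorm(15, 50, 5)
  expect_true(pairedCompare(a + 30, a, "t")$significant)
  expect_equal(pairedCompare(a, a, "t")$p_value, 1)
  expect_error(pairedCompare(a, a, "wilcoxon"), "degenerate")
})

test_that("wilcoxon p-values match exact sign-assignment enumeration", {
  set.seed(8)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    a <- round(rnorm(n, 10, 2), 2)
    b <- round(rnorm(n, 10.5, 2), 2)
    d <- a - b
    if (any(d == 0) || anyDuplicated(abs(d[d != 0]))) next  # need no ties
    expect_equal(pairedCompare(a, b, "wilcoxon")$p_value,
                 signedRankExact(a, b), tolerance = 1e-12)
  }
})

test_that("observer tables flow through the agreement analysis", {
  set.seed(31)
  truthVol <- rep(c(2, 4, 6, 8, 10), each = 4)
  mk <- function(obs, rep_id, sd) {
    data.frame(patient = rep(sprintf("P%d", 1:5), each = 4),
               method = "cine", observer = obs, repeat_id = rep_id,
               slice = rep(seq(1, 40, by = 10), times = 5),
               volume_ml = pmax(0, truthVol + rnorm(20, 0, sd)))
  }
  tb <- rbind(mk("A", 1, 0.2), mk("A", 2, 0.2), mk("B", 1, 0.8))
  intra <- observerAgreement(tb, "cine", "intra")
  inter <- observerAgreement(tb, "cine", "inter")
  expect_s4_class(intra, "AgreementResult")
  expect_equal(intra@nPairs, 20L)
  expect_false(is.na(intra@meanDiffPct))
  # the noisier second observer must not agree better than the repeat
  expect_gt(intra@icc, inter@icc)
  expect_error(observerAgreement(tb[, -1], "cine", "intra"), "columns")
})
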