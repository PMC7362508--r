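#' @include AllClasses.R AllGenerics.R
NULL

#' Bland-Altman analysis of paired measurements
#'
#' Differences are taken as \code{x - y} (first observation or observer
#' minus second). Reports the mean difference (bias), the sample standard
#' deviation (n-1 denominator), and the 95\% limits of agreement at
#' mean +/- 1.96 SD. Percent-scale summaries are filled in when per-pair
#' percent errors are supplied (see \code{\link{percentError}}).
#'
#' @param x,y paired per-slice measurements (ml), equal length >= 2.
#' @param pct optional per-pair percent errors matching \code{x}.
#' @param icc optional ICC to carry in the result (with its category).
#' @return An \code{\linkS4class{AgreementResult}}.
#' @examples
#' blandAltman(c(1, 2, 3, 4), c(1, 1, 4, 4))
#' @export
blandAltman <- function(x, y, pct = NULL, icc = NA_real_) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 2L)
    stop("Bland-Altman needs at least 2 pairs")
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  mp <- NA_real_; sp <- NA_real_
  if (!is.null(pct)) {
    if (length(pct) != length(x))
      stop("pct must match the number of pairs")
    mp <- mean(pct); sp <- stats::sd(pct)
  }
  new("AgreementResult",
      meanDiffMl = m, sdDiffMl = s,
      loaLow = m - 1.96 * s, loaHigh = m + 1.96 * s,
      meanDiffPct = mp, sdDiffPct = sp,
      icc = icc,
      iccCategory = if (is.na(icc)) NA_character_ else interpretICC(icc),
      nPairs = length(x))
}

#' Per-slice measurement error as a percentage of the patient total
#'
#' Each per-slice difference is divided by its patient's total fat
#' volume and scaled to percent. The normalization basis is a choice:
#' here the per-patient mean of the two compared measurements' totals.
#'
#' @param diffMl per-slice differences (ml).
#' @param patient patient id per slice (recycled if length 1).
#' @param patientTotalsMl named vector of per-patient total fat volume
#'   (ml), strictly positive.
#' @return Per-slice percent errors.
#' @examples
#' percentError(c(0.39, 0), c("p1", "p1"), c(p1 = 165))
#' @export
percentError <- function(diffMl, patient, patientTotalsMl) {
  if (length(patient) == 1L) patient <- rep(patient, length(diffMl))
  if (length(patient) != length(diffMl))
    stop("patient must match diffMl")
  patient <- as.character(patient)
  miss <- setdiff(unique(patient), names(patientTotalsMl))
  if (length(miss))
    stop("no total volume for patient ", miss[1L])
  tot <- patientTotalsMl[patient]
  if (any(tot <= 0))
    stop("patient totals must be strictly positive")
  as.numeric(diffMl / tot * 100)
}

#' Intraclass correlation coefficient for two raters
#'
#' Default is the two-way random-effects, absolute-agreement,
#' single-measures coefficient ICC(2,1),
#' \deqn{\frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)},}
#' with \eqn{k = 2} raters, \eqn{n} subjects (here patient-slices), and
#' mean squares from the two-way ANOVA of value on subject and rater
#' (computed via \code{\link[stats]{aov}}). \code{model = "ICC3"} gives
#' the two-way mixed-effects consistency form
#' \eqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E)}.
#'
#' @param x,y the two raters' measurements over the same n >= 3 subjects.
#' @param model "ICC2" (absolute agreement, default) or "ICC3"
#'   (consistency).
#' @return ICC value in [-1, 1]. Identical constant tables (zero total
#'   variance) return 1 with a warning, by convention.
#' @export
icc <- function(x, y, model = c("ICC2", "ICC3")) {
  model <- match.arg(model)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L)
    stop("ICC needs at least 3 paired rows")
  if (anyNA(x) || anyNA(y))
    stop("ICC input must have no missing cells")
  v <- c(x, y)
  if (stats::var(v) == 0) {
    warning("zero total variance; returning ICC = 1 by convention")
    return(1)
  }
  subject <- factor(rep(seq_len(n), 2L))
  rater <- factor(rep(1:2, each = n))
  ms <- summary(stats::aov(v ~ subject + rater))[[1L]][["Mean Sq"]]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  k <- 2
  val <- switch(model,
    ICC2 = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)),
    ICC3 = (msr - mse) / (msr + (k - 1) * mse))
  max(-1, min(1, val))
}

#' Interpret an ICC as an agreement category
#'
#' Below 0.5 is poor, 0.5 up to 0.75 moderate, 0.75 up to 0.9 good, and
#' 0.9 and above excellent; class boundaries belong to the upper class.
#'
#' @param icc coefficient in [-1, 1].
#' @return One of "poor", "moderate", "good", "excellent".
#' @examples
#' interpretICC(0.96)  # excellent
#' interpretICC(0.63)  # moderate
#' @export
interpretICC <- function(icc) {
  if (is.na(icc) || icc < -1 || icc > 1)
    stop("icc must lie in [-1, 1]")
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good"
  else "excellent"
}

#' Body surface area
#'
#' Mosteller: \eqn{\sqrt{h \cdot w / 3600}}; Du Bois:
#' \eqn{0.007184 h^{0.725} w^{0.425}} (height in cm, weight in kg).
#'
#' @param heightCm height in cm, > 0.
#' @param weightKg weight in kg, > 0.
#' @param method "mosteller" (default) or "dubois".
#' @return BSA in square metres.
#' @examples
#' bodySurfaceArea(180, 72)  # sqrt(3.6) ~ 1.897
#' @export
bodySurfaceArea <- function(heightCm, weightKg,
                            method = c("mosteller", "dubois")) {
  method <- match.arg(method)
  if (any(heightCm <= 0) || any(weightKg <= 0))
    stop("height and weight must be positive")
  switch(method,
    mosteller = sqrt(heightCm * weightKg / 3600),
    dubois = 0.007184 * heightCm^0.725 * weightKg^0.425)
}

#' Linear regression of BSA-indexed fat volume on BMI
#'
#' Ordinary least squares of the per-patient epicardial fat volume
#' indexed to body surface area (ml/m^2) on body mass index (kg/m^2),
#' reporting the slope, intercept, coefficient of determination and the
#' two-sided slope p-value (t distribution, n-2 df).
#'
#' @param fatIndexMlPerM2 per-patient BSA-indexed fat volume.
#' @param bmi per-patient BMI.
#' @return List with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_value}.
#' @export
regressBMI <- function(fatIndexMlPerM2, bmi) {
  if (length(fatIndexMlPerM2) != length(bmi))
    stop("inputs must have equal length")
  if (length(bmi) < 3L)
    stop("regression needs at least 3 patients")
  if (stats::var(bmi) == 0)
    stop("BMI is constant; slope undefined")
  fit <- stats::lm(fatIndexMlPerM2 ~ bmi)
  # degenerate (perfect or null) fits are legitimate here; the R^2 and
  # coefficient algebra remain well defined
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  list(slope = unname(co["bmi", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = sm$r.squared,
       p_value = if (nrow(co) > 1L) unname(co["bmi", "Pr(>|t|)"])
                 else NA_real_)
}

#' Paired two-sided comparison of two measurement sets
#'
#' Paired t-test for continuous variables, exact Wilcoxon signed-rank
#' test for non-parametric ones; significance is flagged at P < 0.05.
#' Identical inputs yield p = 1 for the t-test by convention (zero
#' differences carry no evidence); all-zero differences are a degenerate
#' input for the signed-rank test and raise an error.
#'
#' @param a,b paired measurements.
#' @param kind "t" or "wilcoxon".
#' @return List with \code{p_value} and logical \code{significant}.
#' @export
pairedCompare <- function(a, b, kind = c("t", "wilcoxon")) {
  kind <- match.arg(kind)
  if (length(a) != length(b))
    stop("a and b must be paired (equal length)")
  d <- a - b
  if (kind == "t") {
    if (length(d) < 2L) stop("t-test needs at least 2 pairs")
    # zero-variance differences: no evidence if all zero, perfect
    # separation otherwise (t statistic diverges)
    p <- if (all(d == 0)) 1
         else if (stats::sd(d) < 1e-12 * abs(mean(d))) 0
         else stats::t.test(a, b, paired = TRUE)$p.value
  } else {
    if (all(d == 0))
      stop("all paired differences are zero; signed-rank test degenerate")
    p <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE,
                            correct = FALSE)$p.value
  }
  list(p_value = p, significant = p < 0.05)
}

#' Observer agreement from a tidy per-slice measurement table
#'
#' Pivots an observer table (columns \code{patient}, \code{method},
#' \code{observer}, \code{repeat_id}, \code{slice}, \code{volume_ml}) into
#' the two compared measurement vectors and runs Bland-Altman, percent
#' error and ICC in one step. For \code{comparison = "intra"} the two
#' repeats of the first observer are compared; for \code{"inter"} the
#' first repeat of the two observers.
#'
#' @param table data.frame in ObserverTable layout.
#' @param method which acquisition to analyse ("cine" or "single_phase").
#' @param comparison "intra" or "inter".
#' @param iccModel passed to \code{\link{icc}}.
#' @return An \code{\linkS4class{AgreementResult}}.
#' @export
observerAgreement <- function(table, method = c("cine", "single_phase"),
                              comparison = c("intra", "inter"),
                              iccModel = "ICC2") {
  method <- match.arg(method)
  comparison <- match.arg(comparison)
  req <- c("patient", "method", "observer", "repeat_id", "slice", "volume_ml")
  if (!all(req %in% names(table)))
    stop("table must have columns ", paste(req, collapse = ", "))
  tb <- table[table$method == method, , drop = FALSE]
  if (any(tb$volume_ml < 0)) stop("volumes must be >= 0")
  if (comparison == "intra") {
    obs <- sort(unique(tb$observer))[1L]
    tb <- tb[tb$observer == obs, , drop = FALSE]
    reps <- sort(unique(tb$repeat_id))
    if (length(reps) < 2L) stop("intra-observer analysis needs 2 repeats")
    aTb <- tb[tb$repeat_id == reps[1L], ]
    bTb <- tb[tb$repeat_id == reps[2L], ]
  } else {
    obs <- sort(unique(tb$observer))
    if (length(obs) < 2L) stop("inter-observer analysis needs 2 observers")
    reps1 <- min(tb$repeat_id[tb$observer == obs[1L]])
    reps2 <- min(tb$repeat_id[tb$observer == obs[2L]])
    aTb <- tb[tb$observer == obs[1L] & tb$repeat_id == reps1, ]
    bTb <- tb[tb$observer == obs[2L] & tb$repeat_id == reps2, ]
  }
  key <- function(d) paste(d$patient, d$slice, sep = "#")
  common <- intersect(key(aTb), key(bTb))
  if (length(common) < length(key(aTb)) || length(common) < length(key(bTb)))
    stop("paired analysis requires both members of every (patient, slice)")
  aTb <- aTb[match(common, key(aTb)), ]
  bTb <- bTb[match(common, key(bTb)), ]
  x <- aTb$volume_ml; y <- bTb$volume_ml
  totA <- tapply(x, aTb$patient, sum)
  totB <- tapply(y, bTb$patient, sum)
  totals <- (totA + totB[names(totA)]) / 2
  pct <- percentError(x - y, aTb$patient, totals)
  blandAltman(x, y, pct = pct, icc = icc(x, y, model = iccModel))
}
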