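## Method-comparison statistics: Bland-Altman limits of agreement, binned
## Cohen kappa, standard error of measurement, variance-ratio / t /
## Shapiro-Wilk tests (delegated to the standard stats routines) and survey
## summaries.

#' Bland-Altman limits of agreement
#'
#' Pairwise differences \code{d = x - y}; the bias is \code{mean(d)}, the
#' limits of agreement are \code{mean(d) +/- 1.96 sd(d)} with the sample
#' (n-1) standard deviation.  Under a normal difference model the limits
#' bracket about 95\% of the differences.
#'
#' @param x,y equal-length paired measurement vectors (cm)
#' @return a \code{\link{BAResult-class}} object
#' @examples
#' blandAltman(c(42, 43.5, 44), c(42.3, 43.1, 44.6))
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y))
    .stop("cephaloPairingError",
          sprintf("x and y must be paired: lengths %d and %d",
                  length(x), length(y)))
  if (length(x) < 2L)
    .stop("cephaloInsufficientDataError",
          "Bland-Altman needs at least 2 pairs")
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  methods::new("BAResult", meanDiff = m, sdDiff = s,
               loaLower = m - 1.96 * s, loaUpper = m + 1.96 * s,
               n = length(d))
}

#' Bland-Altman plot
#'
#' Scatter of per-pair means against differences with horizontal reference
#' lines at the bias and both limits of agreement.  The device is chosen by
#' the file extension (\code{.png} or \code{.svg}).
#'
#' @param result a \code{\link{BAResult-class}} from \code{\link{blandAltman}}
#' @param x,y the paired vectors the result was computed from
#' @param file output path ending in \code{.png} or \code{.svg}
#' @param main plot title
#' @return \code{file}, invisibly
#' @export
blandAltmanPlot <- function(result, x, y, file, main = "Bland-Altman plot") {
  if (length(x) < 1L || length(x) != length(y))
    .stop("cephaloInsufficientDataError", "no pairs to plot")
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = 720, height = 540),
         svg = grDevices::svg(file, width = 7, height = 5.5),
         .stop("cephaloInvalidArgumentError",
               "file must end in .png or .svg"))
  on.exit(grDevices::dev.off())
  means <- (x + y) / 2; diffs <- x - y
  loa <- limitsOfAgreement(result)
  ylim <- range(c(diffs, loa, meanDiff(result)))
  ylim <- ylim + c(-0.1, 0.1) * max(diff(ylim), 0.5)
  plot(means, diffs, pch = 19, col = "#00000088",
       xlab = "Mean of methods (cm)", ylab = "Difference (cm)",
       main = main, ylim = ylim)
  graphics::abline(h = meanDiff(result), col = "blue", lwd = 2)
  graphics::abline(h = loa, col = "red", lty = 2, lwd = 2)
  invisible(file)
}

#' Cohen kappa for binned continuous measurements
#'
#' Each measurement is assigned to a fixed-width bin
#' \code{[k w, (k+1) w)} anchored at zero (default width 1 cm), and the
#' chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} is
#' computed from the paired bin labels, with \eqn{p_e} from the marginal
#' bin frequencies.  A pre-binned confusion matrix may be supplied instead
#' of raw vectors.
#'
#' @param x,y paired measurement vectors (cm); alternatively \code{x} may
#'   be a square confusion matrix and \code{y} omitted
#' @param binWidthCm bin width in cm
#' @return a \code{\link{KappaResult-class}} object
#' @examples
#' cohenKappa(c(42.2, 43.6, 44.1), c(42.8, 43.4, 45.2))
#' cohenKappa(matrix(c(20, 10, 5, 15), 2))  # pre-binned 2x2 table
#' @export
cohenKappa <- function(x, y = NULL, binWidthCm = 1.0) {
  if (is.matrix(x) && is.null(y)) {
    tab <- x
  } else {
    if (length(x) != length(y))
      .stop("cephaloPairingError", "x and y must be paired")
    if (!is.numeric(binWidthCm) || binWidthCm <= 0)
      .stop("cephaloInvalidArgumentError", "binWidthCm must be > 0")
    bx <- floor(x / binWidthCm); by <- floor(y / binWidthCm)
    lev <- sort(unique(c(bx, by)))
    tab <- table(factor(bx, levels = lev), factor(by, levels = lev))
  }
  N <- sum(tab)
  if (N < 1L)
    .stop("cephaloInsufficientDataError", "no observations")
  po <- sum(diag(as.matrix(tab))) / N
  pe <- sum(rowSums(tab) * colSums(tab)) / N^2
  if (pe >= 1 - 1e-12) {
    if (po >= 1 - 1e-12) kap <- 1
    else .stop("cephaloUndefinedKappaError",
               "expected agreement is 1 but observed agreement is not; kappa undefined")
  } else {
    kap <- (po - pe) / (1 - pe)
  }
  methods::new("KappaResult", kappa = kap, pObserved = po, pExpected = pe,
               binWidthCm = as.numeric(binWidthCm))
}

#' Standard error of measurement
#'
#' \code{SEM = sd * sqrt(1 - icc)}: the typical error attached to a single
#' measurement given the measurements' spread and their reliability.
#' \code{mode = "mean"} instead returns the literal standard error of the
#' mean, \code{sd / sqrt(n)}.
#'
#' @param sdCm standard deviation of the measurements (cm)
#' @param icc reliability estimate (only used for \code{mode =
#'   "measurement"}; must not exceed 1)
#' @param mode \code{"measurement"} (default) or \code{"mean"}
#' @param n sample size (required for \code{mode = "mean"})
#' @return the standard error in cm
#' @examples
#' semMeasurement(2, 0.75)            # 1.0
#' semMeasurement(2, mode = "mean", n = 16)  # 0.5
#' @export
semMeasurement <- function(sdCm, icc = NULL, mode = c("measurement", "mean"),
                           n = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(sdCm) || sdCm < 0)
    .stop("cephaloInvalidArgumentError", "sdCm must be >= 0")
  if (mode == "mean") {
    if (is.null(n) || n < 1)
      .stop("cephaloInvalidArgumentError", "mode='mean' requires n >= 1")
    return(sdCm / sqrt(n))
  }
  if (is.null(icc))
    .stop("cephaloInvalidArgumentError", "mode='measurement' requires icc")
  if (icc > 1)
    .stop("cephaloInvalidArgumentError", "icc cannot exceed 1")
  sdCm * sqrt(1 - icc)
}

#' Variance-ratio (F) test
#'
#' Two-sided F test of equal variances, \code{F = var(x) / var(y)} with
#' degrees of freedom \code{(n_x - 1, n_y - 1)}.
#'
#' @param x,y numeric samples, each of length >= 2
#' @return a \code{\link{TestResult-class}} object
#' @export
varianceRatioTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    .stop("cephaloInsufficientDataError",
          "both samples need at least 2 observations")
  if (stats::var(y) == 0)
    .stop("cephaloDegenerateVarianceError",
          "denominator sample has zero variance")
  ft <- stats::var.test(x, y)
  methods::new("TestResult", statistic = unname(ft$statistic),
               df = unname(ft$parameter), pValue = unname(ft$p.value),
               testName = "f_variance")
}

#' Pooled two-sample t test
#'
#' Equal-variance (pooled) two-sample t test of equal means, two-sided.
#'
#' @param x,y numeric samples, each of length >= 2
#' @return a \code{\link{TestResult-class}} object
#' @export
twoSampleT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    .stop("cephaloInsufficientDataError",
          "both samples need at least 2 observations")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  p <- unname(tt$p.value)
  stat <- unname(tt$statistic)
  if (is.na(p)) p <- 1    # identical constant samples: no evidence either way
  if (is.na(stat)) stat <- 0
  methods::new("TestResult", statistic = stat, df = unname(tt$parameter),
               pValue = p, testName = "t_two_sample")
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric sample, 3 <= n <= 5000
#' @return a \code{\link{TestResult-class}} object with the W statistic
#' @export
shapiroWilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L)
    .stop("cephaloInsufficientDataError",
          "Shapiro-Wilk needs at least 3 observations")
  if (length(x) > 5000L)
    .stop("cephaloInvalidArgumentError",
          "Shapiro-Wilk supports at most 5000 observations")
  if (stats::sd(x) == 0)
    .stop("cephaloDegenerateVarianceError", "sample is constant")
  sw <- stats::shapiro.test(x)
  methods::new("TestResult", statistic = unname(sw$statistic),
               df = numeric(0), pValue = unname(sw$p.value),
               testName = "shapiro_wilk")
}

#' Summarize a survey item count
#'
#' Integer percentage of \code{count} out of \code{n}, rounded to the
#' nearest integer with halves away from zero (so 31 of 37 reports 84\%).
#'
#' @param count respondents selecting the item (0 <= count <= n)
#' @param n total respondents (> 0)
#' @return a \code{\link{SurveySummary-class}} object
#' @examples
#' summarizeSurvey(31, 37)
#' @export
summarizeSurvey <- function(count, n) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != round(n))
    .stop("cephaloInvalidArgumentError", "n must be a positive integer")
  if (!is.numeric(count) || length(count) != 1L || count < 0 ||
      count != round(count))
    .stop("cephaloInvalidArgumentError", "count must be a non-negative integer")
  if (count > n)
    .stop("cephaloInvalidArgumentError", "count cannot exceed n")
  pct <- as.integer(floor(100 * count / n + 0.5))
  methods::new("SurveySummary", count = as.integer(count), n = as.integer(n),
               percent = pct)
}
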