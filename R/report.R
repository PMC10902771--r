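## One-stop agreement report for a two-arm comparison (two methods or two
## raters), bundling ICC, Bland-Altman, kappa, SEM, F, t and Shapiro-Wilk.

#' Full agreement report for one comparison
#'
#' Pairs the measurements of two arms by subject (averaging repeats within
#' an arm), then computes the ICC across the two arms, Bland-Altman limits
#' of agreement (optionally with a plot), binned Cohen kappa, the standard
#' error of measurement \code{sd * sqrt(1 - ICC)} over all paired values,
#' the variance-ratio F test, the pooled two-sample t test, and a
#' Shapiro-Wilk normality check of the per-subject mean values.
#'
#' @param table a \code{\link{MeasurementTable-class}}
#' @param arms length-2 character vector naming the two arms (two method
#'   tags or two rater ids), compared as \code{arms[1] - arms[2]}
#' @param by whether arms are \code{"method"} tags or \code{"rater"} ids
#' @param kappaBinCm bin width for \code{\link{cohenKappa}}
#' @param iccForm ICC form for \code{\link{iccTwoWay}}
#' @param plotFile optional path (\code{.png}/\code{.svg}) for the
#'   Bland-Altman plot
#' @return an \code{\link{AgreementReport-class}} object
#' @examples
#' tbl <- simulateRaterStudy(raterStudySpec(nSubjects = 20, seed = 4))
#' agreementReport(tbl, arms = c("researcher", "parent"), by = "rater")
#' @export
agreementReport <- function(table, arms, by = c("method", "rater"),
                            kappaBinCm = 1.0, iccForm = "2,1",
                            plotFile = NULL) {
  by <- match.arg(by)
  if (length(arms) != 2L)
    .stop("cephaloComparisonSpecError", "exactly two arms must be named")
  d <- if (methods::is(table, "MeasurementTable")) measurements(table)
       else as.data.frame(table)
  if (nrow(d) == 0L)
    .stop("cephaloInsufficientDataError", "empty measurement table")
  armcol <- if (by == "method") d$method else d$rater_id
  for (a in arms)
    if (!a %in% armcol)
      .stop("cephaloComparisonSpecError",
            sprintf("arm '%s' not present in the table (%s column)", a, by))
  d <- d[armcol %in% arms, , drop = FALSE]
  armcol <- if (by == "method") d$method else d$rater_id
  agg <- tapply(d$hc_cm, list(as.character(d$subject_id),
                              factor(armcol, levels = arms)), mean)
  agg <- agg[stats::complete.cases(agg), , drop = FALSE]
  if (nrow(agg) < 2L)
    .stop("cephaloInsufficientDataError",
          "fewer than 2 subjects measured in both arms")
  x <- agg[, 1L]; y <- agg[, 2L]
  pair_df <- data.frame(subject_id = rep(rownames(agg), 2L),
                        rater_id = rep(arms, each = nrow(agg)),
                        method = "app", "repeat" = 1L,
                        hc_cm = c(x, y), check.names = FALSE)
  icc <- iccTwoWay(pair_df, form = iccForm)
  ba <- blandAltman(x, y)
  plotPath <- NA_character_
  if (!is.null(plotFile)) {
    blandAltmanPlot(ba, x, y, plotFile,
                    main = sprintf("Bland-Altman: %s vs %s",
                                   arms[1L], arms[2L]))
    plotPath <- plotFile
  }
  kap <- cohenKappa(x, y, binWidthCm = kappaBinCm)
  sem <- semMeasurement(stats::sd(c(x, y)), iccValue(icc))
  ft <- varianceRatioTest(x, y)
  tt <- twoSampleT(x, y)
  sw <- shapiroWilk((x + y) / 2)
  methods::new("AgreementReport",
               comparison = sprintf("%s vs %s (%s)", arms[1L], arms[2L], by),
               icc = icc, blandAltman = ba, kappa = kap, semCm = sem,
               fTest = ft, tTest = tt, shapiro = sw,
               nPairs = nrow(agg), plotPath = plotPath)
}

.testToList <- function(t) {
  list(test = t@testName, statistic = t@statistic,
       df = if (length(t@df)) t@df else NULL, p_value = t@pValue)
}

.reportToList <- function(r) {
  list(
    comparison = r@comparison,
    n_pairs = r@nPairs,
    icc = list(form = r@icc@form, icc = r@icc@icc,
               ci_95 = c(r@icc@ciLow, r@icc@ciHigh),
               category = r@icc@category,
               var_subject = r@icc@varSubject, var_rater = r@icc@varRater,
               var_error = r@icc@varError),
    bland_altman = list(mean_diff_cm = r@blandAltman@meanDiff,
                        sd_diff_cm = r@blandAltman@sdDiff,
                        loa_lower_cm = r@blandAltman@loaLower,
                        loa_upper_cm = r@blandAltman@loaUpper,
                        n = r@blandAltman@n),
    kappa = list(kappa = r@kappa@kappa, p_observed = r@kappa@pObserved,
                 p_expected = r@kappa@pExpected,
                 bin_width_cm = r@kappa@binWidthCm),
    sem_cm = r@semCm,
    f_test = .testToList(r@fTest),
    t_test = .testToList(r@tTest),
    shapiro_wilk = .testToList(r@shapiro),
    plot = if (!is.na(r@plotPath)) r@plotPath)
}

#' Write an agreement report as JSON
#'
#' @param report an \code{\link{AgreementReport-class}}
#' @param path output JSON path
#' @return \code{path}, invisibly
#' @export
writeAgreementReport <- function(report, path) {
  jsonlite::write_json(.reportToList(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
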