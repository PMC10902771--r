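## Accessor and show methods.

#' @rdname cephalo-accessors
setMethod("hcCm", "HCMeasurement", function(object) object@hcCm)
#' @rdname cephalo-accessors
setMethod("pxPerCm", "ScaleCalibration", function(object) object@pxPerCm)
#' @rdname cephalo-accessors
setMethod("pxPerCm", "HCMeasurement", function(object) object@pxPerCm)
#' @rdname cephalo-accessors
setMethod("semiAxes", "EllipseParams",
          function(object) c(a = object@a, b = object@b))
#' @rdname cephalo-accessors
setMethod("ellipseCenter", "EllipseParams",
          function(object) c(cx = object@cx, cy = object@cy))
#' @rdname cephalo-accessors
setMethod("ellipseTheta", "EllipseParams", function(object) object@theta)
#' @rdname cephalo-accessors
setMethod("fitRMS", "EllipseParams", function(object) object@rms)
#' @rdname cephalo-accessors
setMethod("fitRMS", "HCMeasurement", function(object) object@quality)
#' @rdname cephalo-accessors
setMethod("contourCoords", "Contour", function(object) object@coords)
#' @rdname cephalo-accessors
setMethod("contourArea", "Contour", function(object) object@area)
#' @rdname cephalo-accessors
setMethod("landmarkMatrix", "Landmarks", function(object) {
  m <- rbind(top = object@top, bottom = object@bottom,
             left = object@left, right = object@right)
  colnames(m) <- c("x", "y")
  m
})
#' @rdname cephalo-accessors
setMethod("circularity", "ScaleCalibration", function(object) object@circularity)
#' @rdname cephalo-accessors
setMethod("detectedDiameterPx", "ScaleCalibration",
          function(object) object@detectedDiameterPx)
#' @rdname cephalo-accessors
setMethod("trueHcCm", "GroundTruth", function(object) object@trueHcCm)
#' @rdname cephalo-accessors
setMethod("renderedHcCm", "GroundTruth", function(object) object@renderedHcCm)
#' @rdname cephalo-accessors
setMethod("groundTruthEllipse", "GroundTruth", function(object) object@ellipsePx)
#' @rdname cephalo-accessors
setMethod("groundTruthLandmarks", "GroundTruth",
          function(object) object@landmarksPx)
#' @rdname cephalo-accessors
setMethod("pxPerCm", "GroundTruth", function(object) object@scalePxPerCm)
#' @rdname cephalo-accessors
setMethod("detectedDiameterPx", "GroundTruth",
          function(object) object@refDiameterPx)
#' @rdname cephalo-accessors
setMethod("measurements", "MeasurementTable", function(object) object@data)
#' @rdname cephalo-accessors
setMethod("iccValue", "ICCResult", function(object) object@icc)
#' @rdname cephalo-accessors
setMethod("iccCI", "ICCResult",
          function(object) c(lower = object@ciLow, upper = object@ciHigh))
#' @rdname cephalo-accessors
setMethod("iccBand", "ICCResult", function(object) object@category)
#' @rdname cephalo-accessors
setMethod("varianceComponents", "ICCResult", function(object)
  c(subject = object@varSubject, rater = object@varRater,
    error = object@varError))
#' @rdname cephalo-accessors
setMethod("meanDiff", "BAResult", function(object) object@meanDiff)
#' @rdname cephalo-accessors
setMethod("sdDiff", "BAResult", function(object) object@sdDiff)
#' @rdname cephalo-accessors
setMethod("limitsOfAgreement", "BAResult", function(object)
  c(lower = object@loaLower, upper = object@loaUpper))
#' @rdname cephalo-accessors
setMethod("kappaValue", "KappaResult", function(object) object@kappa)
#' @rdname cephalo-accessors
setMethod("testStatistic", "TestResult", function(object) object@statistic)
#' @rdname cephalo-accessors
setMethod("pValue", "TestResult", function(object) object@pValue)

## -- show methods -----------------------------------------------------------

setMethod("show", "EllipseParams", function(object) {
  cat(sprintf(
    "EllipseParams: center (%.2f, %.2f) px, semi-axes %.2f x %.2f px, theta %.1f deg",
    object@cx, object@cy, object@a, object@b, object@theta * 180 / pi))
  if (is.finite(object@rms)) cat(sprintf(", fit RMS %.3f px", object@rms))
  cat("\n")
})

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour: %d boundary points, area %.0f px^2\n",
              nrow(object@coords), object@area))
})

setMethod("show", "Landmarks", function(object) {
  m <- landmarkMatrix(object)
  cat("Landmarks (px):\n")
  print(round(m, 2))
})

setMethod("show", "ScaleCalibration", function(object) {
  cat(sprintf(
    "ScaleCalibration: %.3f px/cm (reference %.2f px for %.2f cm, circularity %.3f)\n",
    object@pxPerCm, object@detectedDiameterPx, object@knownDiameterCm,
    object@circularity))
})

setMethod("show", "HCMeasurement", function(object) {
  cat(sprintf("HCMeasurement [%s]: HC = %.2f cm (scale %.2f px/cm, fit RMS %.3f px)\n",
              object@method, object@hcCm, object@pxPerCm, object@quality))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %dx%d px @ %.1f px/cm; head %.1f x %.1f cm at (%.1f, %.1f) cm, rot %.0f deg\n",
    object@imageWidthPx, object@imageHeightPx, object@scalePxPerCm,
    object@headSemiMajorCm, object@headSemiMinorCm, object@headCenterCm[1L],
    object@headCenterCm[2L], object@headRotationDeg))
  cat(sprintf(
    "  reference %.1f cm at (%.1f, %.1f) cm; noise SD %.1f, clutter %d, foreshorten %.3f, seed %d\n",
    object@refDiameterCm, object@refCenterCm[1L], object@refCenterCm[2L],
    object@noiseSd, object@clutterCount, object@foreshorten, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: true HC %.3f cm (rendered %.3f cm), ref %.1f px, scale %.1f px/cm\n",
              object@trueHcCm, object@renderedHcCm, object@refDiameterPx,
              object@scalePxPerCm))
})

setMethod("show", "RaterStudySpec", function(object) {
  cat(sprintf(
    "RaterStudySpec: %d subjects ~ N(%.1f, %.1f^2) cm, %d raters x %d repeats, seed %d\n",
    object@nSubjects, object@subjectMeanCm, object@subjectSdCm,
    nrow(object@raters), object@nRepeats, object@seed))
})

setMethod("show", "MeasurementTable", function(object) {
  d <- object@data
  cat(sprintf("MeasurementTable: %d records, %d subjects, %d raters, methods: %s\n",
              nrow(d), length(unique(d$subject_id)),
              length(unique(d$rater_id)),
              paste(sort(unique(d$method)), collapse = ", ")))
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC(%s) = %.3f [95%% CI %.3f, %.3f] - %s reliability (n=%d, k=%d)\n",
              object@form, object@icc, object@ciLow, object@ciHigh,
              object@category, object@n, object@k))
})

setMethod("show", "BAResult", function(object) {
  cat(sprintf("Bland-Altman: mean diff %.3f cm, SD %.3f cm, LoA [%.3f, %.3f] (n=%d)\n",
              object@meanDiff, object@sdDiff, object@loaLower, object@loaUpper,
              object@n))
})

setMethod("show", "KappaResult", function(object) {
  cat(sprintf("Cohen kappa = %.3f (p_o %.3f, p_e %.3f, bin width %.2f cm)\n",
              object@kappa, object@pObserved, object@pExpected,
              object@binWidthCm))
})

setMethod("show", "TestResult", function(object) {
  dfs <- if (length(object@df)) paste(round(object@df, 2), collapse = ", ")
         else "-"
  cat(sprintf("%s: statistic %.4f, df (%s), p = %.4g\n",
              object@testName, object@statistic, dfs, object@pValue))
})

setMethod("show", "SurveySummary", function(object) {
  cat(sprintf("Survey item: %d of %d (%d%%)\n",
              object@count, object@n, object@percent))
})

setMethod("show", "AgreementReport", function(object) {
  cat("AgreementReport:", object@comparison, sprintf("(n pairs = %d)\n",
                                                     object@nPairs))
  show(object@icc)
  show(object@blandAltman)
  show(object@kappa)
  cat(sprintf("SEM = %.3f cm\n", object@semCm))
  show(object@fTest); show(object@tTest); show(object@shapiro)
})
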