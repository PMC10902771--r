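## S4 classes for the phantom simulator, the vision pipeline and the
## agreement statistics.  Constructors with defaults are exported; slots are
## reached through accessors, not `@`.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## Geometry

#' Ellipse parameters in pixel units
#'
#' Center, semi-axes and in-plane rotation of an ellipse in pixel
#' coordinates (origin top-left, x right, y down, angles counter-clockwise
#' from +x).  Canonical form: \code{a >= b > 0}, \code{theta} in [0, pi).
#'
#' @slot cx,cy center (px)
#' @slot a,b semi-major and semi-minor axes (px), \code{a >= b > 0}
#' @slot theta rotation (rad) in [0, pi)
#' @slot rms RMS orthogonal residual of the fit that produced the ellipse
#'   (px); \code{NA} for analytically constructed ellipses
#' @exportClass EllipseParams
setClass("EllipseParams",
  representation(cx = "numeric", cy = "numeric", a = "numeric", b = "numeric",
                 theta = "numeric", rms = "numeric"),
  validity = function(object) {
    if (length(object@a) != 1L || length(object@b) != 1L)
      return("a and b must be single values")
    if (!(object@a >= object@b && object@b > 0))
      return("semi-axes must satisfy a >= b > 0")
    if (object@theta < 0 || object@theta >= pi)
      return("theta must lie in [0, pi)")
    TRUE
  })

#' @rdname EllipseParams-class
#' @param cx,cy,a,b,theta,rms see slots
#' @return an \code{EllipseParams} object
#' @examples
#' ellipseParams(200, 150, a = 120, b = 80, theta = pi / 6)
#' @export
ellipseParams <- function(cx, cy, a, b, theta = 0, rms = NA_real_) {
  theta <- theta %% pi
  if (b > a) {  # canonicalize axis order
    tmp <- a; a <- b; b <- tmp
    theta <- (theta + pi / 2) %% pi
  }
  methods::new("EllipseParams", cx = as.numeric(cx), cy = as.numeric(cy),
               a = as.numeric(a), b = as.numeric(b),
               theta = as.numeric(theta), rms = as.numeric(rms))
}

#' Closed pixel contour of a segmented region
#'
#' @slot coords n x 2 matrix of pixel-center coordinates tracing the closed
#'   outer boundary (first row adjacent to last)
#' @slot area enclosed area in px^2 (pixel count of the region)
#' @exportClass Contour
setClass("Contour",
  representation(coords = "matrix", area = "numeric"),
  validity = function(object) {
    if (ncol(object@coords) != 2L) return("coords must be an n x 2 matrix")
    if (nrow(object@coords) < 5L) return("a contour needs at least 5 points")
    if (object@area <= 0) return("area must be positive")
    TRUE
  })

#' @rdname Contour-class
#' @param coords,area see slots
#' @export
pixelContour <- function(coords, area = .polyArea(coords)) {
  methods::new("Contour", coords = coords, area = as.numeric(area))
}

#' Four manual landmark points
#'
#' The top, bottom and two outermost lateral points of the head outline,
#' supplied by the user to constrain the ellipse fit.
#'
#' @slot top,bottom,left,right length-2 numeric pixel coordinates
#' @exportClass Landmarks
setClass("Landmarks",
  representation(top = "numeric", bottom = "numeric",
                 left = "numeric", right = "numeric"),
  validity = function(object) {
    pts <- list(object@top, object@bottom, object@left, object@right)
    if (any(vapply(pts, length, 1L) != 2L))
      return("each landmark must be a length-2 (x, y) point")
    if (!(object@top[2L] < object@bottom[2L]))
      return("top landmark must lie above the bottom landmark (top.y < bottom.y)")
    if (!(object@left[1L] < object@right[1L]))
      return("left landmark must lie left of the right landmark")
    m <- do.call(rbind, pts)
    if (anyDuplicated(m)) return("landmark points must be distinct")
    TRUE
  })

#' @rdname Landmarks-class
#' @param top,bottom,left,right length-2 (x, y) pixel points
#' @export
landmarks <- function(top, bottom, left, right) {
  out <- try(methods::new("Landmarks", top = as.numeric(top),
                          bottom = as.numeric(bottom), left = as.numeric(left),
                          right = as.numeric(right)), silent = TRUE)
  if (inherits(out, "try-error"))
    .stop("cephaloInvalidLandmarksError", attr(out, "condition")$message)
  out
}

#' Pixel-to-centimeter scale calibration
#'
#' @slot pxPerCm pixels per centimeter, \code{detectedDiameterPx /
#'   knownDiameterCm} exactly
#' @slot knownDiameterCm stated physical diameter of the reference object
#' @slot detectedDiameterPx diameter of the area-equivalent circle of the
#'   detected reference component
#' @slot circularity detection quality \code{4 pi A / P^2} in [0, 1]
#' @exportClass ScaleCalibration
setClass("ScaleCalibration",
  representation(pxPerCm = "numeric", knownDiameterCm = "numeric",
                 detectedDiameterPx = "numeric", circularity = "numeric"),
  validity = function(object) {
    if (object@knownDiameterCm <= 0) return("knownDiameterCm must be > 0")
    if (object@detectedDiameterPx <= 0) return("detectedDiameterPx must be > 0")
    if (abs(object@pxPerCm -
            object@detectedDiameterPx / object@knownDiameterCm) > 1e-12)
      return("pxPerCm must equal detectedDiameterPx / knownDiameterCm")
    if (object@circularity < 0 || object@circularity > 1)
      return("circularity must lie in [0, 1]")
    TRUE
  })

#' A single head-circumference measurement
#'
#' @slot hcCm circumference estimate (cm)
#' @slot method \code{"app"} or \code{"tape"}
#' @slot quality RMS residual of the fused ellipse fit (px)
#' @slot pxPerCm scale used for the conversion
#' @slot ellipse fused \code{EllipseParams}
#' @slot arcLengthCm diagnostic: smoothed pixel-contour arc length / scale
#' @slot warnings character vector of non-fatal notes
#' @exportClass HCMeasurement
setClass("HCMeasurement",
  representation(hcCm = "numeric", method = "character", quality = "numeric",
                 pxPerCm = "numeric", ellipse = "EllipseParams",
                 arcLengthCm = "numeric", warnings = "character"),
  validity = function(object) {
    if (object@hcCm <= 0) return("hcCm must be positive")
    if (!object@method %in% c("app", "tape"))
      return("method must be 'app' or 'tape'")
    TRUE
  })

## ---------------------------------------------------------------------------
## Phantom simulation

#' Specification of a synthetic phantom photograph
#'
#' Defines the rendered scene: a skin-tone head ellipse with speckle
#' texture, a saturated reference disc of known diameter, optional gray
#' distractor polygons, additive Gaussian pixel noise, and an optional
#' out-of-plane tilt modeled as multiplicative foreshortening of the minor
#' axis.
#'
#' @slot imageWidthPx,imageHeightPx image size (px)
#' @slot headCenterCm length-2 head center (cm)
#' @slot headSemiMajorCm,headSemiMinorCm head semi-axes (cm), major >= minor
#' @slot headRotationDeg in-plane rotation in [0, 180)
#' @slot refCenterCm length-2 reference-disc center (cm)
#' @slot refDiameterCm reference diameter (cm)
#' @slot scalePxPerCm rendering scale (px per cm)
#' @slot noiseSd additive Gaussian pixel noise SD on the 8-bit scale
#' @slot clutterCount number of gray distractor polygons
#' @slot foreshorten multiplicative foreshortening of the minor axis in
#'   (0, 1]; 1 = no tilt
#' @slot refColor length-3 RGB in [0, 1] of the reference disc
#' @slot seed RNG seed
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(imageWidthPx = "integer", imageHeightPx = "integer",
                 headCenterCm = "numeric", headSemiMajorCm = "numeric",
                 headSemiMinorCm = "numeric", headRotationDeg = "numeric",
                 refCenterCm = "numeric", refDiameterCm = "numeric",
                 scalePxPerCm = "numeric", noiseSd = "numeric",
                 clutterCount = "integer", foreshorten = "numeric",
                 refColor = "numeric", seed = "integer"),
  validity = function(object) {
    s <- object@scalePxPerCm
    if (object@imageWidthPx < 1L || object@imageHeightPx < 1L)
      return("image dimensions must be positive")
    if (s <= 0) return("scalePxPerCm must be > 0")
    if (!(object@headSemiMajorCm >= object@headSemiMinorCm &&
          object@headSemiMinorCm > 0))
      return("head semi-axes must satisfy major >= minor > 0")
    if (object@headRotationDeg < 0 || object@headRotationDeg >= 180)
      return("headRotationDeg must lie in [0, 180)")
    if (object@refDiameterCm <= 0) return("refDiameterCm must be > 0")
    if (object@refDiameterCm * s < 20)
      return("reference must be resolvable: refDiameterCm * scalePxPerCm >= 20 px")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@clutterCount < 0L) return("clutterCount must be >= 0")
    if (object@foreshorten <= 0 || object@foreshorten > 1)
      return("foreshorten must lie in (0, 1]")
    th <- object@headRotationDeg * pi / 180
    a <- object@headSemiMajorCm * s
    b <- object@headSemiMinorCm * s * object@foreshorten
    hx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
    hy <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
    cx <- object@headCenterCm[1L] * s; cy <- object@headCenterCm[2L] * s
    if (cx - hx < 0 || cx + hx > object@imageWidthPx ||
        cy - hy < 0 || cy + hy > object@imageHeightPx)
      return("head ellipse must lie fully inside the image")
    r <- object@refDiameterCm * s / 2
    rx <- object@refCenterCm[1L] * s; ry <- object@refCenterCm[2L] * s
    if (rx - r < 0 || rx + r > object@imageWidthPx ||
        ry - r < 0 || ry + r > object@imageHeightPx)
      return("reference disc must lie fully inside the image")
    if (sqrt((rx - cx)^2 + (ry - cy)^2) <= a + r)
      return("head ellipse and reference disc must not overlap")
    TRUE
  })

#' @rdname PhantomSpec-class
#' @param imageWidthPx,imageHeightPx,headCenterCm,headSemiMajorCm,headSemiMinorCm,headRotationDeg,refCenterCm,refDiameterCm,scalePxPerCm,noiseSd,clutterCount,foreshorten,refColor,seed
#'   see slots
#' @return a validated \code{PhantomSpec}
#' @examples
#' spec <- phantomSpec(seed = 1)
#' @export
phantomSpec <- function(imageWidthPx = 640L, imageHeightPx = 480L,
                        headCenterCm = c(13, 12), headSemiMajorCm = 7.5,
                        headSemiMinorCm = 6.0, headRotationDeg = 0,
                        refCenterCm = c(26, 6), refDiameterCm = 3.0,
                        scalePxPerCm = 20, noiseSd = 2, clutterCount = 0L,
                        foreshorten = 1, refColor = c(0.10, 0.20, 0.95),
                        seed = 0L) {
  out <- try(methods::new("PhantomSpec",
    imageWidthPx = as.integer(imageWidthPx),
    imageHeightPx = as.integer(imageHeightPx),
    headCenterCm = as.numeric(headCenterCm),
    headSemiMajorCm = as.numeric(headSemiMajorCm),
    headSemiMinorCm = as.numeric(headSemiMinorCm),
    headRotationDeg = as.numeric(headRotationDeg),
    refCenterCm = as.numeric(refCenterCm),
    refDiameterCm = as.numeric(refDiameterCm),
    scalePxPerCm = as.numeric(scalePxPerCm), noiseSd = as.numeric(noiseSd),
    clutterCount = as.integer(clutterCount),
    foreshorten = as.numeric(foreshorten), refColor = as.numeric(refColor),
    seed = as.integer(seed)), silent = TRUE)
  if (inherits(out, "try-error"))
    .stop("cephaloInvalidSpecError", attr(out, "condition")$message)
  out
}

#' Ground truth of a rendered phantom
#'
#' @slot trueHcCm perimeter of the specified head semi-axes in cm (before
#'   any foreshortening), computed by exact elliptic-integral quadrature
#' @slot renderedHcCm perimeter of the ellipse as rendered (after
#'   foreshortening), in cm
#' @slot ellipsePx \code{EllipseParams} of the rendered head
#' @slot landmarksPx \code{Landmarks} on the rendered head boundary
#' @slot refDiameterPx rendered reference diameter (px)
#' @slot scalePxPerCm copy of the spec scale
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(trueHcCm = "numeric", renderedHcCm = "numeric",
                 ellipsePx = "EllipseParams", landmarksPx = "Landmarks",
                 refDiameterPx = "numeric", scalePxPerCm = "numeric"))

#' Specification of a simulated rater study
#'
#' Measurements follow the two-way crossed model
#' \code{HC[i,j,r] = T[i] + b[j] + e[i,j,r]} with subject truths
#' \code{T[i] ~ N(subjectMeanCm, subjectSdCm^2)}, fixed rater biases
#' \code{b[j]} and rater-specific errors \code{e ~ N(0, errorSdCm[j]^2)}.
#'
#' @slot nSubjects number of subjects (>= 1; >= 2 for ICC use)
#' @slot subjectMeanCm,subjectSdCm population of true HC values (cm)
#' @slot raters data.frame with columns \code{rater_id}, \code{bias_cm},
#'   \code{error_sd_cm}
#' @slot nRepeats repeats per subject x rater
#' @slot method method tag stamped on the records
#' @slot seed RNG seed
#' @exportClass RaterStudySpec
setClass("RaterStudySpec",
  representation(nSubjects = "integer", subjectMeanCm = "numeric",
                 subjectSdCm = "numeric", raters = "data.frame",
                 nRepeats = "integer", method = "character", seed = "integer"),
  validity = function(object) {
    if (object@nSubjects < 1L) return("nSubjects must be >= 1")
    if (object@subjectSdCm < 0) return("subjectSdCm must be >= 0")
    if (nrow(object@raters) < 1L) return("at least one rater is required")
    need <- c("rater_id", "bias_cm", "error_sd_cm")
    if (!all(need %in% names(object@raters)))
      return("raters needs columns rater_id, bias_cm, error_sd_cm")
    if (any(object@raters$error_sd_cm < 0))
      return("error_sd_cm must be >= 0 for every rater")
    if (object@nRepeats < 1L) return("nRepeats must be >= 1")
    TRUE
  })

#' @rdname RaterStudySpec-class
#' @param nSubjects,subjectMeanCm,subjectSdCm,raters,nRepeats,method,seed
#'   see slots
#' @export
raterStudySpec <- function(nSubjects = 37L, subjectMeanCm = 45,
                           subjectSdCm = 2,
                           raters = data.frame(
                             rater_id = c("researcher", "parent"),
                             bias_cm = c(0, 0), error_sd_cm = c(0.5, 0.5)),
                           nRepeats = 1L, method = "app", seed = 0L) {
  out <- try(methods::new("RaterStudySpec",
    nSubjects = as.integer(nSubjects), subjectMeanCm = as.numeric(subjectMeanCm),
    subjectSdCm = as.numeric(subjectSdCm), raters = raters,
    nRepeats = as.integer(nRepeats), method = as.character(method),
    seed = as.integer(seed)), silent = TRUE)
  if (inherits(out, "try-error"))
    .stop("cephaloInvalidSpecError", attr(out, "condition")$message)
  out
}

## ---------------------------------------------------------------------------
## Measurement tables and statistics results

#' Long-format table of repeated HC measurements
#'
#' Records of (subject_id, rater_id, method, repeat, hc_cm); the key
#' (subject, rater, method, repeat) must be unique and all values positive.
#'
#' @slot data data.frame with columns \code{subject_id}, \code{rater_id},
#'   \code{method}, \code{repeat}, \code{hc_cm}
#' @exportClass MeasurementTable
setClass("MeasurementTable",
  representation(data = "data.frame"),
  validity = function(object) {
    d <- object@data
    need <- c("subject_id", "rater_id", "method", "repeat", "hc_cm")
    if (!all(need %in% names(d)))
      return(paste("missing columns:",
                   paste(setdiff(need, names(d)), collapse = ", ")))
    if (nrow(d) > 0L) {
      if (any(!is.finite(d$hc_cm)) || any(d$hc_cm <= 0))
        return("hc_cm must be positive and finite")
      if (!all(d$method %in% c("tape", "app")))
        return("method must be 'tape' or 'app'")
      key <- paste(d$subject_id, d$rater_id, d$method, d[["repeat"]], sep = "\r")
      if (anyDuplicated(key)) {
        i <- which(duplicated(key))[1L]
        return(sprintf(
          "duplicated (subject, rater, method, repeat) key: (%s, %s, %s, %s)",
          d$subject_id[i], d$rater_id[i], d$method[i], d[["repeat"]][i]))
      }
    }
    TRUE
  })

#' @rdname MeasurementTable-class
#' @param data data.frame with the five schema columns
#' @export
measurementTable <- function(data) {
  out <- try(methods::new("MeasurementTable",
                          data = as.data.frame(data)), silent = TRUE)
  if (inherits(out, "try-error"))
    .stop("cephaloValidationError", attr(out, "condition")$message)
  out
}

#' Intraclass correlation result
#'
#' @slot icc point estimate (can be negative; never clamped)
#' @slot varSubject,varRater,varError variance components (cm^2, truncated
#'   at zero)
#' @slot ciLow,ciHigh 95\% confidence bounds
#' @slot category interpretation band label
#' @slot form ICC form used, e.g. \code{"2,1"}
#' @slot n,k numbers of subjects and raters
#' @exportClass ICCResult
setClass("ICCResult",
  representation(icc = "numeric", varSubject = "numeric", varRater = "numeric",
                 varError = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 category = "character", form = "character",
                 n = "integer", k = "integer"),
  validity = function(object) {
    if (object@icc > 1 + 1e-12) return("icc cannot exceed 1")
    if (!object@category %in% c("poor", "moderate", "good", "excellent"))
      return("unknown category label")
    TRUE
  })

#' Bland-Altman limits of agreement
#'
#' @slot meanDiff mean difference (cm)
#' @slot sdDiff sample SD (n-1) of the differences (cm)
#' @slot loaLower,loaUpper \code{meanDiff -/+ 1.96 * sdDiff}
#' @slot n number of pairs
#' @exportClass BAResult
setClass("BAResult",
  representation(meanDiff = "numeric", sdDiff = "numeric", loaLower = "numeric",
                 loaUpper = "numeric", n = "integer"),
  validity = function(object) {
    if (object@sdDiff < 0) return("sdDiff must be >= 0")
    if (abs(object@loaLower - (object@meanDiff - 1.96 * object@sdDiff)) > 1e-9 ||
        abs(object@loaUpper - (object@meanDiff + 1.96 * object@sdDiff)) > 1e-9)
      return("limits of agreement must equal meanDiff +/- 1.96 * sdDiff")
    TRUE
  })

#' Cohen kappa on binned continuous measurements
#'
#' @slot kappa chance-corrected agreement in [-1, 1]
#' @slot pObserved,pExpected observed and chance agreement proportions
#' @slot binWidthCm categorization bin width (cm)
#' @exportClass KappaResult
setClass("KappaResult",
  representation(kappa = "numeric", pObserved = "numeric",
                 pExpected = "numeric", binWidthCm = "numeric"),
  validity = function(object) {
    if (object@kappa > 1 + 1e-12 || object@kappa < -1 - 1e-12)
      return("kappa must lie in [-1, 1]")
    if (object@pExpected < 1 - 1e-12 &&
        abs(object@kappa - (object@pObserved - object@pExpected) /
              (1 - object@pExpected)) > 1e-9)
      return("kappa must equal (p_o - p_e) / (1 - p_e)")
    TRUE
  })

#' Hypothesis-test result
#'
#' @slot statistic test statistic (t, F or W)
#' @slot df degrees of freedom (length 1 or 2; empty for Shapiro-Wilk)
#' @slot pValue two-sided p-value
#' @slot testName one of \code{t_two_sample}, \code{f_variance},
#'   \code{shapiro_wilk}
#' @exportClass TestResult
setClass("TestResult",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 testName = "character"),
  validity = function(object) {
    if (object@pValue < 0 || object@pValue > 1)
      return("pValue must lie in [0, 1]")
    if (!object@testName %in% c("t_two_sample", "f_variance", "shapiro_wilk"))
      return("unknown testName")
    TRUE
  })

#' Survey item summary
#'
#' @slot count respondents selecting the item
#' @slot n total respondents
#' @slot percent integer percentage, rounded half away from zero
#' @exportClass SurveySummary
setClass("SurveySummary",
  representation(count = "integer", n = "integer", percent = "integer"),
  validity = function(object) {
    if (object@n <= 0L) return("n must be positive")
    if (object@count < 0L || object@count > object@n)
      return("count must lie in [0, n]")
    TRUE
  })

#' Bundle of agreement statistics for one comparison
#'
#' @slot comparison human-readable description of the two arms
#' @slot icc \code{ICCResult}
#' @slot blandAltman \code{BAResult}
#' @slot kappa \code{KappaResult}
#' @slot semCm standard error of measurement (cm)
#' @slot fTest,tTest,shapiro \code{TestResult}s
#' @slot nPairs number of paired subjects
#' @slot plotPath path of the Bland-Altman plot, or \code{NA}
#' @exportClass AgreementReport
setClass("AgreementReport",
  representation(comparison = "character", icc = "ICCResult",
                 blandAltman = "BAResult", kappa = "KappaResult",
                 semCm = "numeric", fTest = "TestResult", tTest = "TestResult",
                 shapiro = "TestResult", nPairs = "integer",
                 plotPath = "character"))
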