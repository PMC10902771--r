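## The full measurement pipeline: segmentation -> ellipse fit -> landmark
## fusion -> scale calibration -> circumference in cm.

#' Measure head circumference from a photograph
#'
#' Composes the pipeline: \code{\link{segmentHead}} finds the oval
#' candidate, \code{\link{fitEllipse}} fits its contour,
#' \code{\link{fuseLandmarks}} pulls the fit toward the four manual
#' landmark points, \code{\link{detectReference}} recovers the
#' pixels-per-cm scale, and the circumference is the Ramanujan perimeter of
#' the fused ellipse converted to centimeters:
#' \code{hc_cm = ellipsePerimeter(a_px / pxPerCm, b_px / pxPerCm)}.
#'
#' The smoothed arc length of the raw pixel contour (divided by the scale)
#' is reported as a diagnostic in \code{arcLengthCm}; the fitted-ellipse
#' perimeter is the measurement because pixelated contours systematically
#' overestimate the length of smooth boundaries.
#'
#' @param image an RGB EBImage \code{Image} or W x H x 3 array on [0, 1]
#' @param lm a \code{\link{landmarks}} object (or 4 x 2 matrix in
#'   top/bottom/left/right order) marking the head's extremes
#' @param knownDiameterCm physical diameter of the reference object (cm)
#' @param colorSpec reference-colour specification, see
#'   \code{\link{detectReference}}
#' @param landmarkWeight weight of each landmark in contour-point
#'   equivalents
#' @return an \code{\link{HCMeasurement-class}} object
#' @examples
#' ph <- renderPhantom(phantomSpec(seed = 3))
#' m <- measureHC(ph$image, groundTruthLandmarks(ph$truth), 3.0)
#' hcCm(m)
#' @export
measureHC <- function(image, lm, knownDiameterCm,
                      colorSpec = list(target = c(0.10, 0.20, 0.95),
                                       tol = 0.35),
                      landmarkWeight = 100) {
  ct <- segmentHead(image)
  ep0 <- fitEllipse(ct)
  fused <- fuseLandmarks(ep0, lm, ct, landmarkWeight = landmarkWeight)
  cal <- detectReference(image, knownDiameterCm, colorSpec = colorSpec)
  ppc <- pxPerCm(cal)
  hc <- ellipsePerimeter(fused@a / ppc, fused@b / ppc)
  arc <- .polyPerimeter(.smoothContour(contourCoords(ct))) / ppc
  warn <- character(0)
  if (circularity(cal) < 0.9)
    warn <- c(warn, sprintf("reference circularity only %.2f",
                            circularity(cal)))
  methods::new("HCMeasurement", hcCm = hc, method = "app",
               quality = fused@rms, pxPerCm = ppc, ellipse = fused,
               arcLengthCm = arc, warnings = warn)
}

## JSON-ready list form of a measurement (the CLI's output record).
.measurementToList <- function(m) {
  list(hc_cm = m@hcCm,
       px_per_cm = m@pxPerCm,
       ellipse = list(cx = m@ellipse@cx, cy = m@ellipse@cy, a = m@ellipse@a,
                      b = m@ellipse@b, theta = m@ellipse@theta),
       quality = m@quality,
       arc_length_cm = m@arcLengthCm,
       method = m@method,
       warnings = as.list(m@warnings))
}
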