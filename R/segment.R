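## Head segmentation and reference-object detection.
##
## Segmentation: the foreground mask is everything whose colour departs from
## the background (estimated from the image border) by more than a fixed
## RGB distance; after morphological closing, connected components are
## traced and each candidate's outer contour is fitted with an ellipse.
## Only components whose ellipse-fit RMS residual stays below a fraction of
## their equivalent radius count as "oval"; among those the largest area
## wins, ties broken by lower residual.

#' Segment the head-candidate region of an image
#'
#' @param image an RGB EBImage \code{Image} or W x H x 3 array on [0, 1]
#' @param colorTolerance RGB Euclidean distance from the border-estimated
#'   background colour beyond which a pixel is foreground
#' @param residualGate maximal ellipse-fit RMS residual, as a fraction of
#'   the component's area-equivalent radius, for a component to qualify as
#'   oval
#' @param minAreaPx components smaller than this are ignored
#' @return a \code{\link{Contour-class}} tracing the selected component
#' @examples
#' ph <- renderPhantom(phantomSpec(seed = 2))
#' ct <- segmentHead(ph$image)
#' fitEllipse(ct)
#' @export
segmentHead <- function(image, colorTolerance = 0.15, residualGate = 0.05,
                        minAreaPx = 200) {
  img <- .asImageArray(image)
  W <- dim(img)[1L]; H <- dim(img)[2L]
  border <- rbind(
    cbind(img[1L, , 1L], img[1L, , 2L], img[1L, , 3L]),
    cbind(img[W, , 1L], img[W, , 2L], img[W, , 3L]),
    cbind(img[, 1L, 1L], img[, 1L, 2L], img[, 1L, 3L]),
    cbind(img[, H, 1L], img[, H, 2L], img[, H, 3L]))
  bg <- apply(border, 2L, stats::median)
  mask <- .colorDistance(img, bg) > colorTolerance
  if (!any(mask))
    .stop("cephaloNoHeadError", "no foreground found (blank image?)")
  mask <- EBImage::closing(EBImage::Image(mask * 1),
                           EBImage::makeBrush(5L, shape = "disc"))
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(as.integer(EBImage::imageData(lab)))
  ids <- which(areas >= minAreaPx)
  if (!length(ids))
    .stop("cephaloNoHeadError", "no foreground component large enough")
  contours <- EBImage::ocontour(lab)
  cand <- list()
  for (id in ids) {
    oc <- contours[[as.character(id)]]
    if (is.null(oc)) oc <- contours[[id]]
    if (is.null(oc) || nrow(oc) < 5L) next
    xy <- oc + 0.5  # 0-based indices -> pixel-center coordinates
    ep <- try(.fitEllipseCore(xy), silent = TRUE)
    if (inherits(ep, "try-error")) next
    reqv <- sqrt(areas[id] / pi)
    if (ep@rms <= residualGate * reqv)
      cand[[length(cand) + 1L]] <- list(id = id, area = areas[id],
                                        rms = ep@rms, xy = xy)
  }
  if (!length(cand))
    .stop("cephaloNoHeadError",
          "no component passed the ellipse-residual gate")
  areas_c <- vapply(cand, `[[`, 0, "area")
  rms_c <- vapply(cand, `[[`, 0, "rms")
  best <- order(-areas_c, rms_c)[1L]
  pixelContour(cand[[best]]$xy, area = cand[[best]]$area)
}

#' Detect the reference object and calibrate the scale
#'
#' Masks pixels close to the stated reference colour, keeps the connected
#' component with the highest circularity \eqn{4 \pi A / P^2} (which must
#' exceed \code{circularityGate}), and converts the component's
#' area-equivalent diameter to a pixels-per-centimeter scale.
#'
#' @param image an RGB EBImage \code{Image} or W x H x 3 array on [0, 1]
#' @param knownDiameterCm physical diameter of the reference object (cm)
#' @param colorSpec list with \code{target} (length-3 RGB on [0, 1]) and
#'   \code{tol} (RGB distance); default matches the saturated blue disc the
#'   phantom renderer draws
#' @param circularityGate minimal acceptable circularity
#' @param minAreaPx components smaller than this are ignored
#' @return a \code{\link{ScaleCalibration-class}} object
#' @export
detectReference <- function(image, knownDiameterCm,
                            colorSpec = list(target = c(0.10, 0.20, 0.95),
                                             tol = 0.35),
                            circularityGate = 0.85, minAreaPx = 20) {
  if (!is.numeric(knownDiameterCm) || length(knownDiameterCm) != 1L ||
      knownDiameterCm <= 0)
    .stop("cephaloInvalidArgumentError", "knownDiameterCm must be > 0")
  img <- .asImageArray(image)
  mask <- .colorDistance(img, colorSpec$target) < colorSpec$tol
  if (!any(mask))
    .stop("cephaloNoReferenceError",
          "no pixels matching the reference colour")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  areas <- tabulate(as.integer(EBImage::imageData(lab)))
  ids <- which(areas >= minAreaPx)
  if (!length(ids))
    .stop("cephaloNoReferenceError", "reference-coloured blobs too small")
  contours <- EBImage::ocontour(lab)
  best <- NULL
  for (id in ids) {
    oc <- contours[[as.character(id)]]
    if (is.null(oc)) oc <- contours[[id]]
    if (is.null(oc) || nrow(oc) < 5L) next
    ## corner-smoothed polygon perimeter: raw traced pixel chains
    ## overestimate the boundary length of smooth shapes
    P <- .polyPerimeter(.smoothContour(oc + 0.5))
    circ <- min(4 * pi * areas[id] / P^2, 1)
    if (is.null(best) || circ > best$circ)
      best <- list(id = id, circ = circ, area = areas[id])
  }
  if (is.null(best) || best$circ <= circularityGate)
    .stop("cephaloNoReferenceError",
          sprintf("no component with circularity > %.2f", circularityGate))
  d_px <- 2 * sqrt(best$area / pi)
  methods::new("ScaleCalibration",
               pxPerCm = d_px / knownDiameterCm,
               knownDiameterCm = knownDiameterCm,
               detectedDiameterPx = d_px,
               circularity = best$circ)
}
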