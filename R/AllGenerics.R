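## Generics.  Accessor generics are grouped here; pipeline verbs
## (renderPhantom, simulateRaterStudy, measureHC, ...) dispatch on the spec
## or image argument.

#' @name cephalo-accessors
#' @title Accessors for cephalo S4 objects
#' @description Slot access for the package's S4 classes.  Use these rather
#'   than \code{@}.
#' @param object an object of the documented class
#' @param x an object of the documented class
NULL

#' @rdname cephalo-accessors
#' @export
setGeneric("hcCm", function(object) standardGeneric("hcCm"))
#' @rdname cephalo-accessors
#' @export
setGeneric("pxPerCm", function(object) standardGeneric("pxPerCm"))
#' @rdname cephalo-accessors
#' @export
setGeneric("semiAxes", function(object) standardGeneric("semiAxes"))
#' @rdname cephalo-accessors
#' @export
setGeneric("ellipseCenter", function(object) standardGeneric("ellipseCenter"))
#' @rdname cephalo-accessors
#' @export
setGeneric("ellipseTheta", function(object) standardGeneric("ellipseTheta"))
#' @rdname cephalo-accessors
#' @export
setGeneric("fitRMS", function(object) standardGeneric("fitRMS"))
#' @rdname cephalo-accessors
#' @export
setGeneric("contourCoords", function(object) standardGeneric("contourCoords"))
#' @rdname cephalo-accessors
#' @export
setGeneric("contourArea", function(object) standardGeneric("contourArea"))
#' @rdname cephalo-accessors
#' @export
setGeneric("landmarkMatrix", function(object) standardGeneric("landmarkMatrix"))
#' @rdname cephalo-accessors
#' @export
setGeneric("circularity", function(object) standardGeneric("circularity"))
#' @rdname cephalo-accessors
#' @export
setGeneric("detectedDiameterPx",
           function(object) standardGeneric("detectedDiameterPx"))
#' @rdname cephalo-accessors
#' @export
setGeneric("trueHcCm", function(object) standardGeneric("trueHcCm"))
#' @rdname cephalo-accessors
#' @export
setGeneric("renderedHcCm", function(object) standardGeneric("renderedHcCm"))
#' @rdname cephalo-accessors
#' @export
setGeneric("groundTruthEllipse",
           function(object) standardGeneric("groundTruthEllipse"))
#' @rdname cephalo-accessors
#' @export
setGeneric("groundTruthLandmarks",
           function(object) standardGeneric("groundTruthLandmarks"))
#' @rdname cephalo-accessors
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))
#' @rdname cephalo-accessors
#' @export
setGeneric("iccValue", function(object) standardGeneric("iccValue"))
#' @rdname cephalo-accessors
#' @export
setGeneric("iccCI", function(object) standardGeneric("iccCI"))
#' @rdname cephalo-accessors
#' @export
setGeneric("iccBand", function(object) standardGeneric("iccBand"))
#' @rdname cephalo-accessors
#' @export
setGeneric("varianceComponents",
           function(object) standardGeneric("varianceComponents"))
#' @rdname cephalo-accessors
#' @export
setGeneric("meanDiff", function(object) standardGeneric("meanDiff"))
#' @rdname cephalo-accessors
#' @export
setGeneric("sdDiff", function(object) standardGeneric("sdDiff"))
#' @rdname cephalo-accessors
#' @export
setGeneric("limitsOfAgreement",
           function(object) standardGeneric("limitsOfAgreement"))
#' @rdname cephalo-accessors
#' @export
setGeneric("kappaValue", function(object) standardGeneric("kappaValue"))
#' @rdname cephalo-accessors
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))
#' @rdname cephalo-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' Render a synthetic phantom photograph
#'
#' @param spec a \code{\link{phantomSpec}} object
#' @param ... unused
#' @return a list with elements \code{image} (EBImage \code{Image}, 8-bit
#'   RGB values on [0, 1]) and \code{truth} (\code{\link{GroundTruth-class}})
#' @export
setGeneric("renderPhantom", function(spec, ...) standardGeneric("renderPhantom"))

#' Simulate a crossed rater study
#'
#' @param spec a \code{\link{raterStudySpec}} object
#' @param ... unused
#' @return a \code{\link{MeasurementTable-class}}
#' @export
setGeneric("simulateRaterStudy",
           function(spec, ...) standardGeneric("simulateRaterStudy"))
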