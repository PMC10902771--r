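## Synthetic phantom rendering.  A phantom is a deterministic, seeded
## rendering of a skin-tone head ellipse (anti-aliased boundary, speckle
## interior standing in for hair texture), a saturated reference disc of
## known diameter, optional gray distractor polygons, and additive Gaussian
## pixel noise quantized to 8 bits.  Ground truth (ellipse, landmarks,
## scale, exact perimeter) is returned alongside the image.

.SKIN <- c(0.85, 0.62, 0.48)
.BACKGROUND <- c(0.92, 0.92, 0.90)
.CLUTTER_GRAY <- 0.45

## Anti-aliased coverage of an ellipse over the pixel grid (W x H matrices
## of pixel-center coordinates are implicit).  Coverage ~ clamp(0.5 - d, 0, 1)
## with d the approximate signed boundary distance.
.ellipseCoverage <- function(W, H, cx, cy, a, b, theta) {
  x <- matrix(seq_len(W) - 0.5, W, H)
  y <- matrix(rep(seq_len(H) - 0.5, each = W), W, H)
  dx <- x - cx; dy <- y - cy
  cth <- cos(theta); sth <- sin(theta)
  u <- cth * dx + sth * dy
  v <- -sth * dx + cth * dy
  s <- sqrt((u / a)^2 + (v / b)^2)
  r <- sqrt(u^2 + v^2)
  d <- ifelse(s > 0, (1 - 1 / s) * r, -b)  # <0 inside, >0 outside
  pmin(pmax(0.5 - d, 0), 1)
}

## Point-in-polygon mask over the pixel grid (convex polygons only).
.polygonMask <- function(W, H, poly) {
  x <- matrix(seq_len(W) - 0.5, W, H)
  y <- matrix(rep(seq_len(H) - 0.5, each = W), W, H)
  n <- nrow(poly)
  inside <- matrix(TRUE, W, H)
  for (i in seq_len(n)) {
    p1 <- poly[i, ]; p2 <- poly[if (i == n) 1L else i + 1L, ]
    cross <- (p2[1L] - p1[1L]) * (y - p1[2L]) - (p2[2L] - p1[2L]) * (x - p1[1L])
    inside <- inside & (cross >= 0)
  }
  inside
}

## Alpha-composite a coverage matrix of a solid colour onto img (W x H x 3).
.composite <- function(img, coverage, colour) {
  for (ch in 1:3)
    img[, , ch] <- img[, , ch] * (1 - coverage) + colour[ch] * coverage
  img
}

#' @describeIn renderPhantom Render from a \code{PhantomSpec}.
#' @examples
#' ph <- renderPhantom(phantomSpec(seed = 7))
#' trueHcCm(ph$truth)
#' @export
setMethod("renderPhantom", "PhantomSpec", function(spec, ...) {
  v <- methods::validObject(spec, test = TRUE)
  if (!isTRUE(v)) .stop("cephaloInvalidSpecError", v)
  W <- spec@imageWidthPx; H <- spec@imageHeightPx
  s <- spec@scalePxPerCm
  theta <- (spec@headRotationDeg * pi / 180) %% pi
  a <- spec@headSemiMajorCm * s
  b <- spec@headSemiMinorCm * s * spec@foreshorten
  ep <- ellipseParams(spec@headCenterCm[1L] * s, spec@headCenterCm[2L] * s,
                      a, b, theta)
  rcx <- spec@refCenterCm[1L] * s; rcy <- spec@refCenterCm[2L] * s
  rr <- spec@refDiameterCm * s / 2

  img <- .withSeed(spec@seed, {
    img <- array(rep(.BACKGROUND, each = W * H), dim = c(W, H, 3L))
    ## distractor polygons: random small convex quads, kept clear of the
    ## head and the reference so components never merge
    if (spec@clutterCount > 0L) {
      placed <- 0L
      for (k in seq_len(spec@clutterCount * 200L)) {
        ccx <- stats::runif(1, 0, W); ccy <- stats::runif(1, 0, H)
        rad <- stats::runif(1, 0.4, 1.2) * s
        dhead <- sqrt((ccx - ep@cx)^2 + (ccy - ep@cy)^2)
        dref <- sqrt((ccx - rcx)^2 + (ccy - rcy)^2)
        if (dhead < ep@a + rad + 8 || dref < rr + rad + 8) next
        if (ccx - rad < 1 || ccx + rad > W - 1 ||
            ccy - rad < 1 || ccy + rad > H - 1) next
        ang <- sort(stats::runif(4L, 0, 2 * pi))
        poly <- cbind(ccx + rad * cos(ang), ccy + rad * sin(ang))
        img <- .composite(img, .polygonMask(W, H, poly) * 1,
                          rep(.CLUTTER_GRAY, 3L))
        placed <- placed + 1L
        if (placed >= spec@clutterCount) break
      }
      if (placed < spec@clutterCount)
        .stop("cephaloInvalidSpecError",
              "could not place all distractor polygons clear of head and reference")
    }
    ## head: anti-aliased ellipse with interior speckle ("hair" texture)
    cov <- .ellipseCoverage(W, H, ep@cx, ep@cy, ep@a, ep@b, ep@theta)
    img <- .composite(img, cov, .SKIN)
    interior <- cov >= 1
    speckle <- matrix(stats::rnorm(W * H, 0, 0.03), W, H) * interior
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 + speckle)
    ## reference disc (exact circle coverage)
    x <- matrix(seq_len(W) - 0.5, W, H)
    y <- matrix(rep(seq_len(H) - 0.5, each = W), W, H)
    dref <- sqrt((x - rcx)^2 + (y - rcy)^2) - rr
    covr <- pmin(pmax(0.5 - dref, 0), 1)
    img <- .composite(img, covr, spec@refColor)
    ## sensor noise on the 8-bit scale, then quantization
    if (spec@noiseSd > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec@noiseSd / 255),
                         dim = dim(img))
    img
  })
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255

  truth <- methods::new("GroundTruth",
    trueHcCm = ellipsePerimeter(spec@headSemiMajorCm, spec@headSemiMinorCm,
                                method = "exact"),
    renderedHcCm = ellipsePerimeter(a / s, b / s, method = "exact"),
    ellipsePx = ep,
    landmarksPx = .ellipseExtremes(ep),
    refDiameterPx = spec@refDiameterCm * s,
    scalePxPerCm = s)
  list(image = EBImage::Image(img, colormode = "Color"), truth = truth)
})

#' Write / read a phantom image with its ground-truth sidecar
#'
#' The image is written as 8-bit RGB PNG; the spec and ground truth go to a
#' JSON sidecar with the same basename (\code{.json}).
#'
#' @param phantom a list as returned by \code{\link{renderPhantom}}
#' @param path output PNG path
#' @param spec optionally, the \code{PhantomSpec}, stored in the sidecar
#' @return \code{path}, invisibly
#' @export
writePhantom <- function(phantom, path, spec = NULL) {
  img <- .asImageArray(phantom$image)
  png::writePNG(aperm(img, c(2L, 1L, 3L)), path)
  side <- list(
    ground_truth = .groundTruthToList(phantom$truth),
    spec = if (!is.null(spec)) .phantomSpecToList(spec)
  )
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname writePhantom
#' @param path PNG path previously written by \code{writePhantom}
#' @return \code{readPhantom}: a list with \code{image} and (if the sidecar
#'   exists) \code{truth}
#' @export
readPhantom <- function(path) {
  if (!file.exists(path))
    .stop("cephaloIOError", sprintf("image file not found: %s", path))
  arr <- png::readPNG(path)
  img <- EBImage::Image(aperm(arr[, , 1:3, drop = FALSE], c(2L, 1L, 3L)),
                        colormode = "Color")
  out <- list(image = img)
  sp <- .sidecarPath(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(side$ground_truth))
      out$truth <- .groundTruthFromList(side$ground_truth)
  }
  out
}

.groundTruthToList <- function(gt) {
  lm <- landmarkMatrix(gt@landmarksPx)
  list(
    true_hc_cm = gt@trueHcCm,
    rendered_hc_cm = gt@renderedHcCm,
    ellipse_px = list(cx = gt@ellipsePx@cx, cy = gt@ellipsePx@cy,
                      a = gt@ellipsePx@a, b = gt@ellipsePx@b,
                      theta = gt@ellipsePx@theta),
    landmarks_px = list(top = unname(lm["top", ]),
                        bottom = unname(lm["bottom", ]),
                        left = unname(lm["left", ]),
                        right = unname(lm["right", ])),
    ref_diameter_px = gt@refDiameterPx,
    scale_px_per_cm = gt@scalePxPerCm)
}

.groundTruthFromList <- function(x) {
  methods::new("GroundTruth",
    trueHcCm = x$true_hc_cm,
    renderedHcCm = if (!is.null(x$rendered_hc_cm)) x$rendered_hc_cm
                   else NA_real_,
    ellipsePx = ellipseParams(x$ellipse_px$cx, x$ellipse_px$cy,
                              x$ellipse_px$a, x$ellipse_px$b,
                              x$ellipse_px$theta),
    landmarksPx = landmarks(unlist(x$landmarks_px$top),
                            unlist(x$landmarks_px$bottom),
                            unlist(x$landmarks_px$left),
                            unlist(x$landmarks_px$right)),
    refDiameterPx = x$ref_diameter_px,
    scalePxPerCm = x$scale_px_per_cm)
}

.phantomSpecToList <- function(spec) {
  list(image_width_px = spec@imageWidthPx, image_height_px = spec@imageHeightPx,
       head_center_cm = spec@headCenterCm,
       head_semi_major_cm = spec@headSemiMajorCm,
       head_semi_minor_cm = spec@headSemiMinorCm,
       head_rotation_deg = spec@headRotationDeg,
       ref_center_cm = spec@refCenterCm, ref_diameter_cm = spec@refDiameterCm,
       scale_px_per_cm = spec@scalePxPerCm, noise_sd = spec@noiseSd,
       clutter_count = spec@clutterCount, foreshorten = spec@foreshorten,
       ref_color = spec@refColor, seed = spec@seed)
}

.phantomSpecFromList <- function(x) {
  args <- list()
  map <- c(image_width_px = "imageWidthPx", image_height_px = "imageHeightPx",
           head_center_cm = "headCenterCm",
           head_semi_major_cm = "headSemiMajorCm",
           head_semi_minor_cm = "headSemiMinorCm",
           head_rotation_deg = "headRotationDeg", ref_center_cm = "refCenterCm",
           ref_diameter_cm = "refDiameterCm", scale_px_per_cm = "scalePxPerCm",
           noise_sd = "noiseSd", clutter_count = "clutterCount",
           foreshorten = "foreshorten", ref_color = "refColor", seed = "seed")
  for (nm in names(map))
    if (!is.null(x[[nm]])) args[[map[[nm]]]] <- unlist(x[[nm]])
  do.call(phantomSpec, args)
}

#' @describeIn simulateRaterStudy Simulate from a \code{RaterStudySpec}.
#' @examples
#' tbl <- simulateRaterStudy(raterStudySpec(nSubjects = 5, seed = 1))
#' head(measurements(tbl))
#' @export
setMethod("simulateRaterStudy", "RaterStudySpec", function(spec, ...) {
  v <- methods::validObject(spec, test = TRUE)
  if (!isTRUE(v)) .stop("cephaloInvalidSpecError", v)
  n <- spec@nSubjects; k <- nrow(spec@raters); r <- spec@nRepeats
  rec <- .withSeed(spec@seed, {
    truths <- stats::rnorm(n, spec@subjectMeanCm, spec@subjectSdCm)
    subj <- sprintf("S%03d", seq_len(n))
    rows <- vector("list", n * k)
    idx <- 1L
    for (i in seq_len(n)) {
      for (j in seq_len(k)) {
        e <- stats::rnorm(r, 0, spec@raters$error_sd_cm[j])
        rows[[idx]] <- data.frame(
          subject_id = subj[i],
          rater_id = as.character(spec@raters$rater_id[j]),
          method = spec@method,
          "repeat" = seq_len(r),
          hc_cm = truths[i] + spec@raters$bias_cm[j] + e,
          check.names = FALSE)
        idx <- idx + 1L
      }
    }
    do.call(rbind, rows)
  })
  measurementTable(rec)
})

#' Read and write measurement tables
#'
#' CSV with header \code{subject_id,rater_id,method,repeat,hc_cm}, UTF-8,
#' comma-separated.  Schema violations are reported with row numbers.
#'
#' @param path CSV file path
#' @return \code{readMeasurementTable}: a
#'   \code{\link{MeasurementTable-class}}
#' @export
readMeasurementTable <- function(path) {
  if (!file.exists(path))
    .stop("cephaloIOError", sprintf("table file not found: %s", path))
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "rater_id", "method", "repeat", "hc_cm")
  if (!all(need %in% names(d)))
    .stop("cephaloValidationError",
          paste("CSV is missing columns:",
                paste(setdiff(need, names(d)), collapse = ", ")))
  bad <- which(!is.finite(suppressWarnings(as.numeric(d$hc_cm))) |
                 as.numeric(d$hc_cm) <= 0)
  if (length(bad))
    .stop("cephaloValidationError",
          sprintf("invalid hc_cm at row(s): %s",
                  paste(utils::head(bad, 10L), collapse = ", ")))
  d$hc_cm <- as.numeric(d$hc_cm)
  measurementTable(d)
}

#' @rdname readMeasurementTable
#' @param table a \code{MeasurementTable}
#' @export
writeMeasurementTable <- function(table, path) {
  stopifnot(methods::is(table, "MeasurementTable"))
  utils::write.csv(measurements(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
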