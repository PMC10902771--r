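## Internal helpers: classed conditions, seeded RNG scopes, image coercion.
##
## Pixel coordinate convention used throughout the package: origin at the
## top-left image corner, x rightward, y downward, coordinates refer to
## pixel CENTERS.  The pixel stored at array index [ix, iy] (EBImage order:
## first index is x/column, second is y/row) has center (ix - 0.5, iy - 0.5),
## so a W x H image spans [0, W] x [0, H].

#' Signal a classed cephalo error
#'
#' All package errors carry a specific condition class (e.g.
#' \code{"cephaloNoHeadError"}) plus \code{"cephaloError"}, so callers can
#' discriminate failure modes with \code{tryCatch()}.
#' @noRd
.stop <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "cephaloError", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global \code{.Random.seed} so simulation calls do
#' not perturb the caller's RNG stream.
#' @noRd
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    .stop("cephaloInvalidArgumentError", "'seed' must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Coerce an image to a W x H x 3 numeric array in [0, 1]
#'
#' Accepts an EBImage \code{Image} (Color), a W x H x 3 array, or a W x H
#' matrix (expanded to gray RGB).
#' @noRd
.asImageArray <- function(image) {
  if (methods::is(image, "Image")) image <- EBImage::imageData(image)
  if (is.matrix(image)) image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] < 3L) {
    .stop("cephaloInvalidArgumentError",
          "image must be an RGB Image or a W x H x 3 array")
  }
  img <- image[, , 1:3, drop = FALSE]
  storage.mode(img) <- "double"
  if (max(img) > 1 + 1e-8) img <- img / 255
  img
}

## Per-pixel Euclidean distance from each pixel's RGB to a target colour.
.colorDistance <- function(img, target) {
  sqrt((img[, , 1L] - target[1L])^2 +
       (img[, , 2L] - target[2L])^2 +
       (img[, , 3L] - target[3L])^2)
}

## Closed-polygon perimeter of an n x 2 coordinate matrix.
.polyPerimeter <- function(xy) {
  nxt <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
  sum(sqrt(rowSums((nxt - xy)^2)))
}

## Shoelace area of a closed polygon (absolute value).
.polyArea <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  nx <- c(x[-1L], x[1L]); ny <- c(y[-1L], y[1L])
  abs(sum(x * ny - nx * y)) / 2
}

## One pass of closed-curve corner smoothing (each vertex replaced by the
## mean of itself and its two neighbours).  Used to de-staircase traced
## pixel contours before measuring arc length, which otherwise
## overestimates the perimeter of smooth shapes.
.smoothContour <- function(xy, passes = 2L) {
  n <- nrow(xy)
  if (n < 5L) return(xy)
  for (i in seq_len(passes)) {
    prv <- rbind(xy[n, , drop = FALSE], xy[-n, , drop = FALSE])
    nxt <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
    xy <- (prv + xy + nxt) / 3
  }
  xy
}

## Stable hash of a configuration list, for run logging.
.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}
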