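test_that("noiseless parametric points are recovered to 1e-6", {
  t <- seq(0, 2 * pi, length.out = 61)[-61]
  cases <- list(
    list(cx = 200, cy = 200, a = 100, b = 100, theta = 0),
    list(cx = 300, cy = 250, a = 120, b = 80, theta = 30 * pi / 180),
    list(cx = 50.5, cy = 99.25, a = 40, b = 12, theta = 2.8),
    list(cx = 0, cy = 0, a = 7.5, b = 6, theta = pi / 2))
  for (cs in cases) {
    xy <- ellipsePointsAt(t, cs$cx, cs$cy, cs$a, cs$b, cs$theta)
    ep <- fitEllipse(xy)
    expect_equal(unname(ellipseCenter(ep)), c(cs$cx, cs$cy), tolerance = 1e-6)
    expect_equal(unname(semiAxes(ep)), c(cs$a, cs$b), tolerance = 1e-6)
    if (cs$a > cs$b) {
      dth <- abs(ellipseTheta(ep) - cs$theta %% pi)
      expect_lt(min(dth, pi - dth), 1e-6)
    }
    expect_lt(fitRMS(ep), 1e-6)
  }
})

test_that("under-determined or degenerate inputs fail as fit errors", {
  expect_error(fitEllipse(cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))),
               class = "cephaloFitFailureError")
  xy <- cbind(seq_len(30), 2 * seq_len(30) + 1)  # collinear
  expect_error(fitEllipse(xy), class = "cephaloFitFailureError")
})

test_that("landmarks on the current ellipse leave the fused fit unchanged", {
  t <- seq(0, 2 * pi, length.out = 81)[-81]
  xy <- ellipsePointsAt(t, 300, 250, 120, 80, pi / 7)
  ep <- fitEllipse(xy)
  lm <- cephalo:::.ellipseExtremes(ep)
  fused <- fuseLandmarks(ep, lm, pixelContour(xy))
  expect_equal(unname(ellipseCenter(fused)), unname(ellipseCenter(ep)),
               tolerance = 1e-6)
  expect_equal(unname(semiAxes(fused)), unname(semiAxes(ep)),
               tolerance = 1e-6)
})

test_that("landmark fusion repairs a partially occluded contour", {
  ph <- cleanPhantom(seed = 9)
  ct <- segmentHead(ph$image)
  gt <- groundTruthEllipse(ph$truth)
  xy <- contourCoords(ct)
  cy <- ellipseCenter(gt)[["cy"]]; b <- semiAxes(gt)[["b"]]
  keep <- xy[xy[, 2L] > cy - 0.4 * b, , drop = FALSE]  # ~30% occluded top
  trunc <- pixelContour(keep, area = contourArea(ct))
  raw <- fitEllipse(trunc)
  fused <- fuseLandmarks(raw, groundTruthLandmarks(ph$truth), trunc)
  errRaw <- max(abs(semiAxes(raw) / semiAxes(gt) - 1))
  errFused <- max(abs(semiAxes(fused) / semiAxes(gt) - 1))
  expect_lt(errFused, 0.01)
  expect_lt(errFused, errRaw)
})

test_that("invalid landmarks are rejected", {
  expect_error(landmarks(top = c(5, 5), bottom = c(5, 5),
                         left = c(0, 2), right = c(10, 2)),
               class = "cephaloInvalidLandmarksError")
  expect_error(landmarks(top = c(5, 9), bottom = c(5, 1),
                         left = c(0, 5), right = c(10, 5)),
               class = "cephaloInvalidLandmarksError")
  t <- seq(0, 2 * pi, length.out = 20)
  xy <- ellipsePointsAt(t, 0, 0, 10, 5, 0)
  ep <- fitEllipse(xy)
  expect_error(fuseLandmarks(ep, "not landmarks", pixelContour(xy)),
               class = "cephaloInvalidLandmarksError")
})

test_that("ellipse extremal points lie on the boundary at the extreme ordinates", {
  ep <- ellipseParams(100, 80, a = 50, b = 30, theta = 0.7)
  lm <- landmarkMatrix(cephalo:::.ellipseExtremes(ep))
  res <- cephalo:::.ellipseResiduals(ep, lm)
  expect_lt(max(res), 1e-9)
  t <- seq(0, 2 * pi, length.out = 2000)
  bnd <- ellipsePointsAt(t, 100, 80, 50, 30, 0.7)
  expect_equal(lm["top", "y"], min(bnd[, 2L]), tolerance = 1e-4)
  expect_equal(lm["bottom", "y"], max(bnd[, 2L]), tolerance = 1e-4)
  expect_equal(lm["left", "x"], min(bnd[, 1L]), tolerance = 1e-4)
  expect_equal(lm["right", "x"], max(bnd[, 1L]), tolerance = 1e-4)
})
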