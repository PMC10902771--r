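test_that("rendered geometry follows px = cm x scale exactly", {
  ph <- cleanPhantom(seed = 0)
  gt <- ph$truth
  expect_equal(unname(semiAxes(groundTruthEllipse(gt))), c(150, 120))
  expect_equal(detectedDiameterPx(gt), 60)
  expect_equal(pxPerCm(gt), 20)
  expect_equal(dim(ph$image), c(640L, 480L, 3L))
})

test_that("rendering is deterministic given the seed", {
  spec <- phantomSpec(seed = 42L, noiseSd = 5, clutterCount = 3L)
  a <- renderPhantom(spec)
  b <- renderPhantom(spec)
  expect_identical(EBImage::imageData(a$image), EBImage::imageData(b$image))
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  writePhantom(a, f1, spec = spec); writePhantom(b, f2, spec = spec)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c_ <- renderPhantom(phantomSpec(seed = 43L, noiseSd = 5, clutterCount = 3L))
  expect_false(identical(EBImage::imageData(a$image),
                         EBImage::imageData(c_$image)))
})

test_that("ground-truth perimeter matches the quadrature oracle to 1e-9", {
  for (ax in list(c(7.5, 6.0), c(6.5, 6.2))) {
    ph <- renderPhantom(phantomSpec(headSemiMajorCm = ax[1L],
                                    headSemiMinorCm = ax[2L], seed = 1))
    expect_equal(trueHcCm(ph$truth), oraclePerimeter(ax[1L], ax[2L]),
                 tolerance = 1e-9)
  }
})

test_that("ground-truth landmarks lie on the rendered boundary within 1 px", {
  ph <- renderPhantom(phantomSpec(seed = 2, headRotationDeg = 25,
                                  foreshorten = 0.98))
  gt <- groundTruthEllipse(ph$truth)
  lm <- landmarkMatrix(groundTruthLandmarks(ph$truth))
  expect_lt(max(cephalo:::.ellipseResiduals(gt, lm)), 1)
})

test_that("foreshortening shrinks only the rendered minor axis", {
  ph <- renderPhantom(phantomSpec(seed = 1, foreshorten = 0.95))
  ax <- semiAxes(groundTruthEllipse(ph$truth))
  expect_equal(unname(ax), c(150, 120 * 0.95))
  expect_equal(trueHcCm(ph$truth), oraclePerimeter(7.5, 6.0),
               tolerance = 1e-9)   # true HC is pre-tilt
  expect_equal(renderedHcCm(ph$truth), oraclePerimeter(7.5, 6.0 * 0.95),
               tolerance = 1e-9)
})

test_that("invalid phantom geometry is rejected", {
  # head sticking out of the image
  expect_error(phantomSpec(headCenterCm = c(2, 12)),
               class = "cephaloInvalidSpecError")
  # head and reference overlapping
  expect_error(phantomSpec(refCenterCm = c(14, 12)),
               class = "cephaloInvalidSpecError")
  # unresolvable reference
  expect_error(phantomSpec(refDiameterCm = 0.5),
               class = "cephaloInvalidSpecError")
  expect_error(phantomSpec(headSemiMajorCm = 5, headSemiMinorCm = 6),
               class = "cephaloInvalidSpecError")
})

test_that("phantom round-trips through PNG + JSON sidecar", {
  spec <- phantomSpec(seed = 8, noiseSd = 3)
  ph <- renderPhantom(spec)
  f <- tempfile(fileext = ".png")
  writePhantom(ph, f, spec = spec)
  back <- readPhantom(f)
  expect_equal(EBImage::imageData(back$image), EBImage::imageData(ph$image),
               tolerance = 1e-9)
  expect_equal(trueHcCm(back$truth), trueHcCm(ph$truth), tolerance = 1e-12)
  expect_equal(landmarkMatrix(groundTruthLandmarks(back$truth)),
               landmarkMatrix(groundTruthLandmarks(ph$truth)),
               tolerance = 1e-9)
})
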