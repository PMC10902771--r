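test_that("Bland-Altman on identical methods collapses to zero", {
  x <- c(42.1, 43.7, 44.9, 41.3)
  r <- blandAltman(x, x)
  expect_equal(meanDiff(r), 0)
  expect_equal(unname(limitsOfAgreement(r)), c(0, 0))
})

test_that("Bland-Altman matches direct arithmetic on a toy difference set", {
  r <- blandAltman(c(1, 2, 3), c(0, 0, 0))
  expect_equal(meanDiff(r), 2)
  expect_equal(sdDiff(r), 1)
  expect_equal(unname(limitsOfAgreement(r)), c(2 - 1.96, 2 + 1.96))
})

test_that("limits of agreement cover ~95% of normal differences", {
  set.seed(123)
  d <- rnorm(1e5)
  r <- blandAltman(d, rep(0, 1e5))
  loa <- limitsOfAgreement(r)
  cover <- mean(d >= loa[1L] & d <= loa[2L])
  expect_lt(abs(cover - 0.95), 0.005)
})

test_that("pairing and sample-size violations are rejected", {
  expect_error(blandAltman(1:3, 1:4), class = "cephaloPairingError")
  expect_error(blandAltman(1, 2), class = "cephaloInsufficientDataError")
})

test_that("the Bland-Altman plot writes deterministic files", {
  x <- c(42.1, 43.7, 44.9); y <- c(42.5, 43.1, 45.3)
  r <- blandAltman(x, y)
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  blandAltmanPlot(r, x, y, f1)
  blandAltmanPlot(r, x, y, f2)
  expect_true(file.exists(f1) && file.size(f1) > 0)
  expect_identical(readLines(f1), readLines(f2))
  fp <- tempfile(fileext = ".png")
  blandAltmanPlot(r, x, y, fp)
  expect_true(file.size(fp) > 0)
  expect_error(blandAltmanPlot(r, numeric(0), numeric(0), f1),
               class = "cephaloInsufficientDataError")
})

test_that("kappa handles perfect, tabulated and chance-level agreement", {
  x <- c(40.2, 41.7, 43.3, 45.9)
  expect_equal(kappaValue(cohenKappa(x, x)), 1)
  ## hand computation: p_o = 35/50 = 0.7, p_e = (30*25 + 20*25)/2500 = 0.5
  tab <- matrix(c(20, 10, 5, 15), 2L)
  r <- cohenKappa(tab)
  expect_equal(r@pObserved, 0.7)
  expect_equal(r@pExpected, 0.5)
  expect_equal(kappaValue(r), 0.4)
  set.seed(31)
  a <- runif(20000, 0, 50); b <- runif(20000, 0, 50)
  expect_lt(abs(kappaValue(cohenKappa(a, b))), 0.02)
})

test_that("kappa is invariant to a common shift of the bin labels", {
  set.seed(5)
  x <- rnorm(200, 45, 2); y <- x + rnorm(200, 0, 0.8)
  k1 <- kappaValue(cohenKappa(x, y))
  k2 <- kappaValue(cohenKappa(x + 7, y + 7))  # relabels every bin
  expect_equal(k1, k2, tolerance = 1e-12)
  expect_lte(k1, 1)
})

test_that("degenerate kappa cases follow the stated convention", {
  ## all pairs in one shared bin: chance agreement is 1, kappa defined as 1
  expect_equal(kappaValue(cohenKappa(c(40.1, 40.2), c(40.3, 40.4))), 1)
  tab <- matrix(c(0, 0, 0, 3), 2L)  # single concentrated diagonal cell
  expect_equal(kappaValue(cohenKappa(tab)), 1)
  expect_error(cohenKappa(matrix(0, 2L, 2L)),
               class = "cephaloInsufficientDataError")
})

test_that("SEM follows sd * sqrt(1 - ICC) and decreases in ICC", {
  expect_equal(semMeasurement(1, 0), 1)
  expect_equal(semMeasurement(2, 0.75), 1)
  expect_equal(semMeasurement(3.3, 1), 0)
  grid <- seq(0, 1, by = 0.1)
  vals <- vapply(grid, function(i) semMeasurement(2, i), 0)
  expect_true(all(diff(vals) < 0))
  expect_equal(semMeasurement(2, mode = "mean", n = 16), 0.5)
  expect_error(semMeasurement(1, 1.2), class = "cephaloInvalidArgumentError")
})

test_that("t and F statistics match hand-computed values", {
  ## pooled t for (1,2,3) vs (2,3,4): t = -1 * sqrt(3/2), df = 4
  tt <- twoSampleT(c(1, 2, 3), c(2, 3, 4))
  expect_equal(testStatistic(tt), -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt@df, 4)
  t0 <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(testStatistic(t0), 0)
  expect_equal(pValue(t0), 1)
  x <- c(0, 2, 4); y <- c(0, 1, 2)   # var 4 vs var 1
  ft <- varianceRatioTest(x, y)
  expect_equal(testStatistic(ft), 4)
  expect_equal(ft@df, c(2, 2))
  f1 <- varianceRatioTest(y, y)
  expect_equal(testStatistic(f1), 1)
  expect_error(varianceRatioTest(x, c(1, 1, 1)),
               class = "cephaloDegenerateVarianceError")
})

test_that("t and F type-I error rates sit at the nominal 5%", {
  set.seed(77)
  reps <- 10000L
  pt <- pf <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(50); y <- rnorm(50)
    pt[i] <- pValue(twoSampleT(x, y))
    pf[i] <- pValue(varianceRatioTest(x, y))
  }
  se3 <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(pt < 0.05) - 0.05), se3)
  expect_lt(abs(mean(pf < 0.05) - 0.05), se3)
})

test_that("Shapiro-Wilk behaves sanely on normal and bimodal samples", {
  set.seed(11)
  r <- shapiroWilk(rnorm(500))
  expect_true(testStatistic(r) > 0 && testStatistic(r) <= 1)
  bim <- c(rnorm(250, -4, 0.3), rnorm(250, 4, 0.3))
  expect_lt(pValue(shapiroWilk(bim)), 0.05)
  expect_error(shapiroWilk(c(1, 2)), class = "cephaloInsufficientDataError")
})

test_that("survey percentages round halves away from zero", {
  expect_equal(summarizeSurvey(31, 37)@percent, 84L)
  expect_equal(summarizeSurvey(33, 37)@percent, 89L)
  expect_equal(summarizeSurvey(0, 12)@percent, 0L)
  expect_equal(summarizeSurvey(1, 8)@percent, 13L)   # 12.5 -> 13
  expect_error(summarizeSurvey(38, 37), class = "cephaloInvalidArgumentError")
})

test_that("the agreement report bundles every block and is deterministic", {
  spec <- raterStudySpec(nSubjects = 20L,
                         raters = data.frame(rater_id = c("researcher",
                                                          "parent"),
                                             bias_cm = c(0, 0.3),
                                             error_sd_cm = c(0.4, 0.6)),
                         seed = 6)
  tbl <- simulateRaterStudy(spec)
  rep_ <- agreementReport(tbl, arms = c("researcher", "parent"), by = "rater")
  lst <- cephalo:::.reportToList(rep_)
  expect_setequal(
    setdiff(names(lst), c("comparison", "n_pairs", "plot")),
    c("icc", "bland_altman", "kappa", "sem_cm", "f_test", "t_test",
      "shapiro_wilk"))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writeAgreementReport(rep_, f1)
  writeAgreementReport(agreementReport(tbl, arms = c("researcher", "parent"),
                                       by = "rater"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("comparing an arm with itself degenerates as expected", {
  tbl <- simulateRaterStudy(raterStudySpec(nSubjects = 12L, seed = 8))
  d <- measurements(tbl)
  d2 <- d
  d2$method <- "tape"
  both <- measurementTable(rbind(d, d2))
  rep_ <- agreementReport(both, arms = c("app", "tape"), by = "method")
  expect_equal(iccValue(rep_@icc), 1, tolerance = 1e-12)
  expect_equal(kappaValue(rep_@kappa), 1)
  expect_equal(meanDiff(rep_@blandAltman), 0)
})

test_that("a missing arm is a comparison-spec error", {
  tbl <- simulateRaterStudy(raterStudySpec(nSubjects = 5L, seed = 2))
  expect_error(agreementReport(tbl, arms = c("app", "tape"), by = "method"),
               class = "cephaloComparisonSpecError")
})
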