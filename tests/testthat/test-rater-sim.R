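test_that("the simulated table has the expected crossed structure", {
  spec <- raterStudySpec(nSubjects = 5L,
                         raters = data.frame(rater_id = c("a", "b"),
                                             bias_cm = 0, error_sd_cm = 0.5),
                         nRepeats = 2L, seed = 1)
  tbl <- simulateRaterStudy(spec)
  d <- measurements(tbl)
  expect_equal(nrow(d), 20L)
  expect_setequal(unique(d$rater_id), c("a", "b"))
  expect_equal(sort(unique(d[["repeat"]])), c(1L, 2L))
})

test_that("zero error and zero bias reproduce each subject's truth exactly", {
  spec <- raterStudySpec(nSubjects = 8L,
                         raters = data.frame(rater_id = c("a", "b"),
                                             bias_cm = 0, error_sd_cm = 0),
                         nRepeats = 3L, seed = 2)
  d <- measurements(simulateRaterStudy(spec))
  spread <- tapply(d$hc_cm, d$subject_id, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("rater bias shifts measurements additively", {
  spec <- raterStudySpec(nSubjects = 50L,
                         raters = data.frame(rater_id = c("a", "b"),
                                             bias_cm = c(0, 1.5),
                                             error_sd_cm = 0),
                         nRepeats = 1L, seed = 3)
  d <- measurements(simulateRaterStudy(spec))
  byR <- tapply(d$hc_cm, d$rater_id, mean)
  expect_equal(unname(byR["b"] - byR["a"]), 1.5, tolerance = 1e-12)
})

test_that("sample moments converge to the specified parameters", {
  spec <- raterStudySpec(nSubjects = 10000L, subjectMeanCm = 45,
                         subjectSdCm = 2,
                         raters = data.frame(rater_id = "a", bias_cm = 0,
                                             error_sd_cm = 0.5),
                         nRepeats = 1L, seed = 4)
  d <- measurements(simulateRaterStudy(spec))
  tot_sd <- sqrt(2^2 + 0.5^2)
  se <- tot_sd / sqrt(10000)
  expect_lt(abs(mean(d$hc_cm) - 45), 3 * se)
  expect_lt(abs(sd(d$hc_cm) - tot_sd), 3 * tot_sd / sqrt(2 * 9999))
})

test_that("simulation is reproducible under its seed", {
  s <- raterStudySpec(nSubjects = 10L, seed = 7)
  expect_identical(measurements(simulateRaterStudy(s)),
                   measurements(simulateRaterStudy(s)))
})

test_that("invalid study specs are rejected", {
  expect_error(raterStudySpec(nSubjects = 0L),
               class = "cephaloInvalidSpecError")
  expect_error(raterStudySpec(raters = data.frame(rater_id = "a",
                                                  bias_cm = 0,
                                                  error_sd_cm = -1)),
               class = "cephaloInvalidSpecError")
})

test_that("measurement tables round-trip through CSV", {
  tbl <- simulateRaterStudy(raterStudySpec(nSubjects = 6L, seed = 5))
  f <- tempfile(fileext = ".csv")
  writeMeasurementTable(tbl, f)
  expect_identical(readLines(f, n = 1L),
                   "subject_id,rater_id,method,repeat,hc_cm")
  back <- readMeasurementTable(f)
  expect_equal(measurements(back)$hc_cm, measurements(tbl)$hc_cm,
               tolerance = 1e-9)
})
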