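test_that("identical raters give ICC 1, excellent", {
  m <- cbind(40 + 1:10, 40 + 1:10)
  r <- iccTwoWay(tableFromMatrix(m))
  expect_equal(iccValue(r), 1, tolerance = 1e-12)
  expect_identical(iccBand(r), "excellent")
})

test_that("the estimator equals brute-force sums of squares on small tables", {
  set.seed(20)
  for (rep_ in 1:8) {
    n <- sample(3:10, 1L); k <- sample(2:4, 1L)
    m <- matrix(45 + rnorm(n * k, sd = 2), n, k) +
      outer(rep(0, n), rnorm(k, sd = 0.5), `+`)
    r <- iccTwoWay(tableFromMatrix(m))
    expect_equal(iccValue(r), oracleICC21(m), tolerance = 1e-10)
  }
})

test_that("a 6x2 toy table reproduces the independently computed value", {
  ## frozen from the explicit sum-of-squares oracle (oracleICC21)
  m <- matrix(c(41.2, 43.5, 44.1, 39.8, 42.0, 45.3,
                41.8, 43.1, 44.9, 40.2, 41.5, 45.9), ncol = 2)
  r <- iccTwoWay(tableFromMatrix(m))
  expect_equal(iccValue(r), 0.96348706, tolerance = 1e-7)
  expect_equal(unname(iccCI(r)), c(0.7995139, 0.9946840), tolerance = 1e-6)
})

test_that("repeats are averaged into cells before the ANOVA", {
  d <- tableFromMatrix(cbind(c(40, 42, 44), c(41, 42, 45)))
  d2 <- d
  d2[["repeat"]] <- 2L
  d2$hc_cm <- d2$hc_cm + c(0.4, -0.4, 0.2, -0.2, 0.6, -0.6)
  both <- rbind(d, d2)
  avg <- d
  avg$hc_cm <- (d$hc_cm + d2$hc_cm) / 2
  expect_equal(iccValue(iccTwoWay(both)), iccValue(iccTwoWay(avg)),
               tolerance = 1e-12)
})

test_that("ICC forms are ordered as expected when raters are biased", {
  set.seed(4)
  truth <- rnorm(40, 45, 2)
  m <- cbind(truth + rnorm(40, 0, 0.4), truth + 1 + rnorm(40, 0, 0.4))
  tab <- tableFromMatrix(m)
  agree <- iccValue(iccTwoWay(tab, form = "2,1"))
  consist <- iccValue(iccTwoWay(tab, form = "3,1"))
  expect_gt(consist, agree)  # consistency forgives the fixed offset
  avg <- iccValue(iccTwoWay(tab, form = "2,k"))
  expect_gt(avg, agree)      # averaging improves reliability
})

test_that("insufficient or incomplete designs raise informative errors", {
  expect_error(iccTwoWay(tableFromMatrix(matrix(1:2, 1L))),
               class = "cephaloInsufficientDataError")
  d <- tableFromMatrix(cbind(c(40, 42, 44), c(41, 42, 45)))
  d <- d[-2L, ]  # drop subject S02 for rater R1
  expect_error(iccTwoWay(d), class = "cephaloMissingCellError")
  expect_error(iccTwoWay(d), "S02")
})

test_that("interpretation bands follow the lower-bound-inclusive rule", {
  expect_identical(iccCategory(0.177), "poor")
  expect_identical(iccCategory(-0.3), "poor")
  expect_identical(iccCategory(0.5), "moderate")
  expect_identical(iccCategory(0.749), "moderate")
  expect_identical(iccCategory(0.75), "good")
  expect_identical(iccCategory(0.9), "good")
  expect_identical(iccCategory(0.901), "excellent")
  expect_identical(iccCategory(1), "excellent")
  expect_error(iccCategory(1.2), class = "cephaloInvalidArgumentError")
})

test_that("within-rater ICC across repeats works for a single rater", {
  set.seed(9)
  truth <- rnorm(30, 45, 2)
  d <- data.frame(subject_id = rep(sprintf("S%02d", 1:30), 2L),
                  rater_id = "r1", method = "app",
                  "repeat" = rep(1:2, each = 30L),
                  hc_cm = c(truth + rnorm(30, 0, 0.5),
                            truth + rnorm(30, 0, 0.5)),
                  check.names = FALSE)
  r <- iccTwoWay(d, columns = "repeat")
  expect_gt(iccValue(r), 0.8)
  expect_error(iccTwoWay(rbind(d, within(d, rater_id <- "r2")),
                         columns = "repeat"),
               class = "cephaloInvalidArgumentError")
})
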