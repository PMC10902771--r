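## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: the perimeter oracle integrates the full
## parametric arc length (the package evaluates 4 a E(e) over a quarter
## period), and the ICC oracle spells out the two-way sums of squares.

## Arc length of the ellipse x = a cos t, y = b sin t over a full period.
oraclePerimeter <- function(a, b) {
  stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                   0, 2 * pi, rel.tol = 1e-12, subdivisions = 500L)$value
}

## Points on a rotated ellipse at parameter angles t.
ellipsePointsAt <- function(t, cx, cy, a, b, theta) {
  cbind(cx + a * cos(theta) * cos(t) - b * sin(theta) * sin(t),
        cy + a * sin(theta) * cos(t) + b * cos(theta) * sin(t))
}

## Brute-force ICC(2,1) from explicit sums of squares on an n x k matrix.
oracleICC21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  SSR <- 0
  for (i in seq_len(n)) SSR <- SSR + k * (mean(m[i, ]) - grand)^2
  SSC <- 0
  for (j in seq_len(k)) SSC <- SSC + n * (mean(m[, j]) - grand)^2
  SSE <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    SSE <- SSE + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

## A measurement data.frame from an n x k matrix (subjects x raters).
tableFromMatrix <- function(m, method = "app") {
  n <- nrow(m); k <- ncol(m)
  data.frame(subject_id = rep(sprintf("S%02d", seq_len(n)), k),
             rater_id = rep(sprintf("R%d", seq_len(k)), each = n),
             method = method, "repeat" = 1L, hc_cm = c(m),
             check.names = FALSE)
}

## Default phantom used in several vision tests.
cleanPhantom <- function(seed = 1L, ...) {
  renderPhantom(phantomSpec(seed = seed, noiseSd = 0, clutterCount = 0L, ...))
}
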