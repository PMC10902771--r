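## Intraclass correlation from two-way ANOVA mean squares.
##
## The default form is ICC(2,1): two-way random effects, absolute
## agreement, single measurement.  That matches a design in which every
## rater (or method) measures every subject and raters are regarded as a
## random sample, and in which systematic rater offsets should count
## against reliability - the situation of comparing absolute HC values.
## Other Shrout-Fleiss / McGraw-Wong forms are available behind `form`.

.ICC_FORMS <- c("1,1", "2,1", "3,1", "2,k", "3,k")

## Two-way mean squares of an n x k complete matrix.
.anovaMeanSquares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rmean <- rowMeans(m); cmean <- colMeans(m)
  MSR <- k * sum((rmean - grand)^2) / (n - 1)               # subjects
  MSC <- if (k > 1) n * sum((cmean - grand)^2) / (k - 1) else 0
  resid <- m - outer(rmean, rep(1, k)) - outer(rep(1, n), cmean) + grand
  MSE <- if (k > 1) sum(resid^2) / ((n - 1) * (k - 1)) else 0
  MSW <- if (k > 1) (sum((m - rmean)^2)) / (n * (k - 1)) else 0
  list(MSR = MSR, MSC = MSC, MSE = MSE, MSW = MSW, n = n, k = k)
}

#' Two-way intraclass correlation coefficient
#'
#' Estimates the ICC of a crossed subjects-by-raters design from ANOVA mean
#' squares.  With \code{form = "2,1"} (default),
#' \deqn{ICC = \frac{MS_S - MS_E}{MS_S + (k-1) MS_E + k (MS_R - MS_E)/n},}
#' where \eqn{MS_S}, \eqn{MS_R}, \eqn{MS_E} are the subject, rater and
#' residual mean squares.  The 95\% confidence interval follows the
#' McGraw-Wong F-based construction; for the average-measures forms the
#' single-measure interval is stepped up by the Spearman-Brown relation.
#' Duplicate cells (several repeats of one subject x rater) are averaged
#' before the ANOVA.  Negative point estimates are reported as computed,
#' never clamped.
#'
#' @param table a \code{\link{MeasurementTable-class}} (or plain data.frame
#'   with the same columns)
#' @param raters optional character vector restricting the rater set
#' @param method optional method tag (\code{"app"} or \code{"tape"}) to
#'   filter on; when two methods are present and \code{columns = "method"},
#'   the methods play the role of raters
#' @param columns what forms the columns of the crossed design:
#'   \code{"rater"} (default), \code{"method"}, or \code{"repeat"}
#'   (within-rater reliability across repeats; requires a single rater or
#'   \code{raters} of length 1)
#' @param form ICC form: one of \code{"1,1"}, \code{"2,1"}, \code{"3,1"},
#'   \code{"2,k"}, \code{"3,k"}
#' @param conf confidence level for the interval
#' @return an \code{\link{ICCResult-class}} object
#' @examples
#' tbl <- simulateRaterStudy(raterStudySpec(nSubjects = 30, seed = 1))
#' iccTwoWay(tbl)
#' @export
iccTwoWay <- function(table, raters = NULL, method = NULL,
                      columns = c("rater", "method", "repeat"),
                      form = "2,1", conf = 0.95) {
  columns <- match.arg(columns)
  if (!form %in% .ICC_FORMS)
    .stop("cephaloInvalidArgumentError",
          paste("form must be one of:", paste(.ICC_FORMS, collapse = ", ")))
  d <- if (methods::is(table, "MeasurementTable")) measurements(table)
       else as.data.frame(table)
  if (!is.null(method)) d <- d[d$method %in% method, , drop = FALSE]
  if (!is.null(raters)) d <- d[d$rater_id %in% raters, , drop = FALSE]
  colvar <- switch(columns, rater = d$rater_id, method = d$method,
                   "repeat" = d[["repeat"]])
  if (columns == "repeat" && length(unique(d$rater_id)) > 1L)
    .stop("cephaloInvalidArgumentError",
          "within-rater ICC across repeats needs a single rater; use 'raters='")
  cells <- tapply(d$hc_cm, list(as.character(d$subject_id),
                                as.character(colvar)), mean)
  if (is.null(dim(cells)) || nrow(cells) < 2L)
    .stop("cephaloInsufficientDataError",
          "ICC needs at least 2 subjects")
  if (ncol(cells) < 2L)
    .stop("cephaloInsufficientDataError",
          "ICC needs at least 2 raters/columns")
  if (anyNA(cells)) {
    miss <- which(is.na(cells), arr.ind = TRUE)
    nm <- apply(miss, 1L, function(i)
      paste0("(", rownames(cells)[i[1L]], ", ", colnames(cells)[i[2L]], ")"))
    .stop("cephaloMissingCellError",
          paste("design is not fully crossed; missing cells:",
                paste(utils::head(nm, 10L), collapse = ", ")))
  }
  ms <- .anovaMeanSquares(cells)
  n <- ms$n; k <- ms$k
  MSR <- ms$MSR; MSC <- ms$MSC; MSE <- ms$MSE; MSW <- ms$MSW
  icc <- switch(form,
    "1,1" = (MSR - MSW) / (MSR + (k - 1) * MSW),
    "2,1" = (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n),
    "3,1" = (MSR - MSE) / (MSR + (k - 1) * MSE),
    "2,k" = (MSR - MSE) / (MSR + (MSC - MSE) / n),
    "3,k" = (MSR - MSE) / MSR)
  ci <- .iccConfint(form, MSR, MSC, MSE, MSW, n, k, conf)
  methods::new("ICCResult", icc = icc,
               varSubject = max((MSR - MSE) / k, 0),
               varRater = max((MSC - MSE) / n, 0),
               varError = max(MSE, 0),
               ciLow = ci[1L], ciHigh = ci[2L],
               category = iccCategory(min(icc, 1)),
               form = form, n = as.integer(n), k = as.integer(k))
}

## McGraw-Wong 95% intervals for the single-measure forms; average-measure
## forms via the Spearman-Brown step-up of the single-measure bounds.
.iccConfint <- function(form, MSR, MSC, MSE, MSW, n, k, conf) {
  alpha <- 1 - conf
  sb <- function(x) k * x / (1 + (k - 1) * x)
  single <- switch(substr(form, 1L, 1L),
    "1" = {
      Fo <- MSR / MSW
      FL <- Fo / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
      FU <- Fo * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
      c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    },
    "2" = {
      icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
      a <- k * icc / (n * (1 - icc))
      b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
      v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
      FL <- stats::qf(1 - alpha / 2, n - 1, v)
      FU <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      hi <- n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
      c(lo, hi)
    },
    "3" = {
      Fo <- MSR / MSE
      FL <- Fo / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      FU <- Fo * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    })
  if (endsWith(form, "k")) single <- sb(single)
  pmin(pmax(single, -1), 1)
}

#' Interpretation band of an ICC value
#'
#' Reliability bands: below 0.5 poor, 0.5 to below 0.75 moderate, 0.75 to
#' 0.9 good, above 0.9 excellent.  Boundaries belong to the band whose
#' lower bound they are (0.5 is moderate, 0.75 is good); 0.9 itself is
#' good, only values strictly above 0.9 are excellent.  Negative estimates
#' are poor.
#'
#' @param icc an ICC point estimate (must not exceed 1)
#' @return one of \code{"poor"}, \code{"moderate"}, \code{"good"},
#'   \code{"excellent"}
#' @examples
#' iccCategory(0.177)  # "poor"
#' iccCategory(0.901)  # "excellent"
#' @export
iccCategory <- function(icc) {
  if (!is.numeric(icc) || length(icc) != 1L || is.na(icc))
    .stop("cephaloInvalidArgumentError", "icc must be a single number")
  if (icc > 1 + 1e-9)
    .stop("cephaloInvalidArgumentError", "icc cannot exceed 1")
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
}
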