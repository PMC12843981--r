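# Zero-power extrapolation: the corner frequency is linear in transmitted
# power (APD voltage); its intercept at zero power is the residual corner
# frequency reporting the electrostatic protein-surface interaction.

#' Linear fit of corner frequency versus power with zero-power intercept
#'
#' Ordinary least squares of corner frequency on the abscissa (mean APD
#' voltage of the trapped segment, or laser power in mW). Negative
#' intercepts are valid and returned as-is: a negative zero-power corner
#' frequency measures how much confining potential would have to be added
#' to cancel a net repulsive surface interaction. With exactly 2 points the
#' line is exact and standard errors are reported as `NA`.
#'
#' @param abscissa APD voltages (V) or laser powers (mW); >= 2 distinct,
#'   non-negative values.
#' @param fcHz fitted corner frequencies (Hz), one per abscissa.
#' @param abscissaKind `"apd_voltage_v"` (default) or `"laser_power_mw"`.
#' @param label free-text sample label (e.g. "iron-free, bare gold").
#' @param weights optional inverse-variance weights (per-point fc standard
#'   errors are not reported by the instrument, so the default is
#'   unweighted).
#' @return A [ZeroPowerFit-class].
#' @export
fitZeroPower <- function(abscissa, fcHz, abscissaKind = c("apd_voltage_v",
                                                          "laser_power_mw"),
                         label = "", weights = NULL) {
  abscissaKind <- match.arg(abscissaKind)
  stopifnot(length(abscissa) == length(fcHz), all(is.finite(abscissa)),
            all(is.finite(fcHz)), all(abscissa >= 0))
  if (length(abscissa) < 2L) stop("need at least 2 points")
  if (length(unique(abscissa)) < 2L) stop("all abscissae identical")
  n <- length(abscissa)
  fit <- stats::lm(fcHz ~ abscissa, weights = weights)
  co <- stats::coef(fit)
  if (n > 2L) {
    # summary.lm (also via vcov) warns on exactly collinear input; perfect
    # series are valid here
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    se <- c(NA_real_, NA_real_)
    r2 <- 1
  }
  new("ZeroPowerFit",
      slope = unname(co[2]), intercept = unname(co[1]),
      stderrSlope = unname(se[2]), stderrIntercept = unname(se[1]),
      rSquared = r2, nPoints = as.integer(n),
      abscissaKind = abscissaKind, sampleLabel = label)
}

#' Confidence interval for the zero-power corner frequency
#'
#' Student-t interval for the intercept of a [ZeroPowerFit-class].
#'
#' @param fit a [ZeroPowerFit-class] with at least 3 points.
#' @param level confidence level (default 0.95).
#' @return `c(lower, upper)` in Hz.
#' @export
zeroPowerInterval <- function(fit, level = 0.95) {
  stopifnot(is(fit, "ZeroPowerFit"))
  if (is.na(fit@stderrIntercept))
    stop("standard errors undefined (2-point fit)")
  tq <- stats::qt(1 - (1 - level) / 2, df = fit@nPoints - 2L)
  fit@intercept + c(-1, 1) * tq * fit@stderrIntercept
}

#' Compare the zero-power corner frequencies of two samples
#'
#' The physically meaningful comparison is on magnitude: a larger
#' `|intercept|` indicates a stronger electrostatic surface interaction
#' (e.g. iron-bound versus iron-free protein). Reports the magnitude
#' difference, the signed difference, and a z-like score (magnitude
#' difference over the root-sum-square of the intercept standard errors).
#' No p-value is attached.
#'
#' @param a,b [ZeroPowerFit-class] objects.
#' @return A list with `magnitudeDifference` (Hz, `|a| - |b|`),
#'   `signedDifference` (Hz), `score` (`NA` when either fit has undefined
#'   standard errors), and `largerMagnitude` (`"a"`, `"b"` or `"tie"`,
#'   with sample labels when set).
#' @export
compareZeroPower <- function(a, b) {
  stopifnot(is(a, "ZeroPowerFit"), is(b, "ZeroPowerFit"))
  magDiff <- abs(a@intercept) - abs(b@intercept)
  score <- if (is.na(a@stderrIntercept) || is.na(b@stderrIntercept))
    NA_real_
  else if (magDiff == 0) 0
  else magDiff / sqrt(a@stderrIntercept^2 + b@stderrIntercept^2)
  larger <- if (magDiff > 0) "a" else if (magDiff < 0) "b" else "tie"
  if (larger != "tie") {
    lab <- if (larger == "a") a@sampleLabel else b@sampleLabel
    if (nzchar(lab)) larger <- lab
  }
  list(magnitudeDifference = magDiff,
       signedDifference = a@intercept - b@intercept,
       score = score, largerMagnitude = larger)
}
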