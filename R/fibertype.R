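#' Pearson correlation with two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Fit the carnosine vs percent type-II area calibration
#'
#' Ordinary least squares of carnosine (mM) on percent type-II fiber area,
#' the direction in which the biopsy calibration is plotted; fiber-type
#' estimates for new subjects are then obtained by inverse regression from
#' this one object (see [predictFtArea()]). The residual SD uses the n - 2
#' denominator.
#'
#' @param ftAreaPct percent type-II fiber areas (predictor).
#' @param carnosineMM carnosine concentrations, mM (response).
#' @return a [CalibrationModel-class].
#' @examples
#' set.seed(1)
#' x <- runif(12, 29, 62)
#' m <- fitCalibration(x, 3.4 + 0.034 * x + rnorm(12, 0, 0.35))
#' m@slope
#' @export
fitCalibration <- function(ftAreaPct, carnosineMM) {
  if (length(ftAreaPct) != length(carnosineMM)) stop("lengths differ")
  keep <- !(is.na(ftAreaPct) | is.na(carnosineMM))
  x <- ftAreaPct[keep]; y <- carnosineMM[keep]
  if (length(x) < 3L) stop("need at least 3 calibration pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  fit <- stats::lm(y ~ x)
  co <- pearsonCorrelation(x, y)
  res <- stats::residuals(fit)
  n <- length(x)
  new("CalibrationModel",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r = co$r, pValue = co$p_value, n = as.integer(n),
      residualSd = sqrt(sum(res^2) / (n - 2)),
      xMean = mean(x), yMean = mean(y),
      sxx = sum((x - mean(x))^2))
}

#' Estimate percent type-II fiber area from carnosine
#'
#' Inverse regression on the fitted calibration: the point estimate is
#' `x = (y - intercept) / slope`, and the interval is the classical
#' (Fieller-type) calibration interval obtained by inverting the prediction
#' band of the calibration line — it propagates both the residual scatter of
#' a new measurement and the uncertainty of the fitted line, so a point
#' estimate alone never hides the small-n calibration uncertainty.
#' Estimates outside [0, 100] percent are clamped and flagged.
#'
#' @param model a [CalibrationModel-class].
#' @param carnosine concentration(s), mM (> 0).
#' @param level confidence level of the prediction interval (default 0.95).
#' @return data.frame with `estimate`, `lower`, `upper` (percent type-II
#'   area) and logical `clamped`.
#' @examples
#' set.seed(1)
#' x <- runif(12, 29, 62)
#' m <- fitCalibration(x, 3.4 + 0.034 * x + rnorm(12, 0, 0.35))
#' predictFtArea(m, 5.5)
#' @export
predictFtArea <- function(model, carnosine, level = 0.95) {
  stopifnot(is(model, "CalibrationModel"))
  if (any(is.na(carnosine)) || any(carnosine <= 0))
    stop("'carnosine' must be > 0")
  if (model@slope == 0) stop("calibration uninformative: slope is zero")
  b <- model@slope; s <- model@residualSd; n <- model@n
  est <- (carnosine - model@intercept) / b
  if (s == 0) {
    lower <- upper <- est        # exact calibration: width 0
  } else {
    tq <- stats::qt(1 - (1 - level) / 2, n - 2)
    g <- (tq * s)^2 / (b^2 * model@sxx)
    if (g >= 1) {
      # slope not distinguishable from zero at this level: unbounded interval
      lower <- rep(-Inf, length(est))
      upper <- rep(Inf, length(est))
    } else {
      d <- est - model@xMean
      half <- (tq * s / abs(b)) *
        sqrt(d^2 / model@sxx + (1 - g) * (1 + 1 / n))
      lower <- model@xMean + (d - half) / (1 - g)
      upper <- model@xMean + (d + half) / (1 - g)
    }
  }
  clamped <- est < 0 | est > 100 |
    (is.finite(lower) & lower < 0) | (is.finite(upper) & upper > 100)
  if (any(clamped))
    warning("fiber-type estimate(s) outside [0, 100] % were clamped")
  clamp <- function(v) pmin(pmax(v, 0), 100)
  data.frame(estimate = clamp(est),
             lower = ifelse(is.finite(lower), clamp(lower), 0),
             upper = ifelse(is.finite(upper), clamp(upper), 100),
             clamped = clamped)
}

#' Map carnosine axis ticks to percent type-II area ticks
#'
#' The secondary-axis construction: element-wise inverse regression of tick
#' values through the calibration line; strictly monotone for a positive
#' slope.
#'
#' @param model a [CalibrationModel-class].
#' @param tickValues carnosine tick positions, mM.
#' @return percent type-II area tick positions.
#' @export
carnosineAxisToFtAxis <- function(model, tickValues) {
  stopifnot(is(model, "CalibrationModel"))
  if (model@slope == 0) stop("calibration uninformative: slope is zero")
  (tickValues - model@intercept) / model@slope
}
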