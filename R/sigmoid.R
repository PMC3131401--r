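#' Fit the four-parameter logistic of Z-score vs running distance
#'
#' Least-squares fit of
#' `z = bottom + (top - bottom) / (1 + (d / d50)^hill)`,
#' a sigmoid on the log10 distance axis with its midpoint directly readable
#' as `d50` in meters. Levenberg-Marquardt with multi-start initialization
#' (d50 grid 300/1000/3000 m plus the data median, two hill starts) to avoid
#' local minima; R-squared is reported on the fitted points.
#'
#' The model is invariant to point order and, up to the unit of `d50`, to
#' expressing distance in km instead of m.
#'
#' @param distances best running distances, m (> 0).
#' @param z Z-scores, same length; at least 5 points (4 parameters).
#' @return a [SigmoidModel-class]; non-convergence is flagged via
#'   `@converged`, never hidden.
#' @examples
#' truth <- SigmoidModel(1.2, -0.9, 1000, 3)
#' d <- c(100, 200, 400, 800, 1500, 3000, 10000, 42195)
#' fit <- fitSigmoid(d, predictZ(truth, d))
#' fit@d50
#' @export
fitSigmoid <- function(distances, z) {
  if (length(distances) != length(z)) stop("lengths differ")
  keep <- !(is.na(distances) | is.na(z))
  distances <- distances[keep]
  z <- z[keep]
  if (any(distances <= 0)) stop("all distances must be > 0")
  if (length(z) < 5L)
    stop("at least 5 points are needed to fit 4 parameters")
  ld <- log10(distances)
  if (diff(range(ld)) < 1)
    warning("distances span less than one decade; d50 is poorly constrained")

  model <- function(par) {
    # par: top, bottom, log10(d50), hill
    par[2] + (par[1] - par[2]) / (1 + 10^(par[4] * (ld - par[3])))
  }
  resid <- function(par) model(par) - z

  top0 <- max(z); bot0 <- min(z)
  l50Starts <- unique(c(log10(c(300, 1000, 3000)), stats::median(ld)))
  best <- NULL
  for (l50 in l50Starts) for (h0 in c(1, 3)) {
    fit <- try(minpack.lm::nls.lm(
      par = c(top0, bot0, l50, h0), fn = resid,
      lower = c(-Inf, -Inf, min(ld) - 2, 0.01),
      upper = c(Inf, Inf, max(ld) + 2, 50),
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10,
                                           ftol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("sigmoid fit failed from every start")
  par <- best$par
  sst <- sum((z - mean(z))^2)
  r2 <- if (sst > 0) 1 - best$deviance / sst else NA_real_
  new("SigmoidModel", top = par[1], bottom = par[2], d50 = 10^par[3],
      hill = par[4], rSquared = r2, converged = best$info %in% 1:3)
}

#' Evaluate a sigmoid model at given distances
#'
#' Strictly decreasing in distance when `top > bottom` and `hill > 0`:
#' short-distance specialists sit at the `top` asymptote, marathoners at
#' `bottom`, and `z(d50) = (top + bottom) / 2`.
#'
#' @param model a [SigmoidModel-class].
#' @param distance distances in m (> 0); vectorized.
#' @return predicted Z-score(s).
#' @export
predictZ <- function(model, distance) {
  stopifnot(is(model, "SigmoidModel"))
  if (any(is.na(distance)) || any(distance <= 0))
    stop("'distance' must be > 0")
  model@bottom + (model@top - model@bottom) /
    (1 + (distance / model@d50)^model@hill)
}
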