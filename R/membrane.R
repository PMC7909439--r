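#' Pointwise membrane retention from paired SEC chromatograms
#'
#' Computes the observed retention `R_x = 1 - A_p,x / A_r,x` at every
#' elution time shared by a permeate and a retentate chromatogram recorded
#' in total recirculation mode. The permeate trace is linearly interpolated
#' onto the retentate time grid (same-time ratios are required; acquisition
#' grids may differ). Points where the retentate absorbance falls below
#' `threshold * max(A_r)` are dropped: the ratio is noise-dominated at
#' trace edges.
#'
#' Retentions outside `[0, 1]` (measurement noise) are kept: clipping
#' before the regression would bias the fitted line. Clipping happens only
#' when a calibration is evaluated, in [retention_at()].
#'
#' @param permeate,retentate [chromatogram()]s of the two outlets, recorded
#'   at the same wavelength.
#' @param column_cal A [column_calibration()] assigning a molar mass to
#'   each elution time.
#' @param threshold Signal threshold as a fraction of the retentate
#'   maximum, in (0, 1). Default 0.02.
#' @return A data frame of class `"retention_series"` with columns
#'   `time_min`, `mw_gmol`, `retention`, `a_p`, `a_r`.
#' @export
pointwise_retention <- function(permeate, retentate, column_cal,
                                threshold = 0.02) {
  stopifnot(inherits(permeate, "chromatogram"),
            inherits(retentate, "chromatogram"),
            inherits(column_cal, "column_calibration"))
  if (!isTRUE(all.equal(permeate$wavelength, retentate$wavelength)))
    stop("permeate and retentate were recorded at different wavelengths",
         call. = FALSE)
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold > 0 && threshold < 1))
    stop("`threshold` must be a fraction in (0, 1)", call. = FALSE)
  a_p <- stats::approx(permeate$time, permeate$absorbance,
                       xout = retentate$time, rule = 1)$y
  a_r <- retentate$absorbance
  keep <- !is.na(a_p) & a_r >= threshold * max(a_r)
  if (!any(keep))
    stop("no points retained above the signal threshold", call. = FALSE)
  mw <- as.numeric(mw_at_time(column_cal, retentate$time))
  out <- data.frame(time_min = retentate$time[keep],
                    mw_gmol = mw[keep],
                    retention = 1 - a_p[keep] / a_r[keep],
                    a_p = a_p[keep], a_r = a_r[keep])
  class(out) <- c("retention_series", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Membrane sieving calibration (linear retention-vs-log10 MW law)
#'
#' `membrane_calibration()` builds a calibration from known coefficients of
#' the law `R = slope * log10(MW) + intercept`; `fit_membrane_calibration()`
#' estimates the coefficients by ordinary least squares from a
#' [pointwise_retention()] series. Predicted retentions are clipped to
#' `[0, 1]` at evaluation time.
#'
#' @param slope Retention change per decade of molar mass; must be
#'   non-negative (retention increases with solute size). A zero slope is
#'   accepted so that an idealised fully-transmitting membrane
#'   (`slope = 0, intercept = 0`) can be represented; fitting and
#'   [apparent_mwco()] require a strictly positive slope.
#' @param intercept Dimensionless intercept.
#' @param r_squared Fit diagnostic (optional).
#' @param mwco_nominal Manufacturer molecular-weight cut-off label, g/mol
#'   (optional).
#' @param fit_mw_window Molar-mass range spanned by the fitted points
#'   (optional).
#' @return An object of class `"membrane_calibration"`.
#' @examples
#' cal <- membrane_calibration(0.7978, -1.6206, mwco_nominal = 1000)
#' retention_at(cal, 653)
#' apparent_mwco(cal)
#' @export
membrane_calibration <- function(slope, intercept, r_squared = NA_real_,
                                 mwco_nominal = NULL, fit_mw_window = NULL) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope < 0)
    stop("`slope` must be a non-negative scalar (retention increases with molar mass)",
         call. = FALSE)
  structure(list(slope = as.numeric(slope),
                 intercept = as.numeric(intercept),
                 r_squared = as.numeric(r_squared),
                 mwco_nominal = mwco_nominal,
                 fit_mw_window = fit_mw_window,
                 fit = NULL, series = NULL),
            class = "membrane_calibration")
}

#' @param series A `"retention_series"` from [pointwise_retention()] with
#'   at least 3 points spanning a non-degenerate molar-mass range.
#' @param mw_window Optional molar-mass window `c(min, max)`; only points
#'   inside it enter the regression. Restricting the fit to the SEC
#'   column's validity window avoids points whose molar mass is
#'   extrapolated and where the linear sieving law saturates.
#' @rdname membrane_calibration
#' @export
fit_membrane_calibration <- function(series, mw_window = NULL,
                                     mwco_nominal = NULL) {
  stopifnot(inherits(series, "retention_series"))
  if (!is.null(mw_window))
    series <- series[series$mw_gmol >= mw_window[1L] &
                     series$mw_gmol <= mw_window[2L], , drop = FALSE]
  if (nrow(series) < 3L)
    stop("at least 3 retained points are needed for the regression",
         call. = FALSE)
  lmw <- log10(series$mw_gmol)
  if (diff(range(lmw)) < 1e-8)
    stop("degenerate molar-mass range: retention cannot be regressed on log10(MW)",
         call. = FALSE)
  fit <- stats::lm(retention ~ lmw,
                   data = data.frame(retention = series$retention, lmw = lmw))
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0)
    stop("fitted slope is not positive: retention does not increase with molar mass",
         call. = FALSE)
  # computed directly (not via summary.lm, which warns on noiseless fits)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((series$retention - mean(series$retention))^2)
  cal <- membrane_calibration(slope, unname(stats::coef(fit)[1L]),
                              r_squared = r2,
                              mwco_nominal = mwco_nominal,
                              fit_mw_window = range(series$mw_gmol))
  cal$fit <- fit
  cal$series <- series
  cal
}

#' @export
print.membrane_calibration <- function(x, ...) {
  cat(sprintf("Membrane calibration: R = %g * log10(MW) %+g\n",
              x$slope, x$intercept))
  if (is.finite(x$r_squared)) cat(sprintf("  r_squared = %.4f\n", x$r_squared))
  if (!is.null(x$mwco_nominal))
    cat(sprintf("  nominal MWCO = %g g/mol\n", x$mwco_nominal))
  if (!is.null(x$fit_mw_window))
    cat(sprintf("  fitted over %.4g-%.4g g/mol (%d points)\n",
                x$fit_mw_window[1L], x$fit_mw_window[2L],
                if (is.null(x$series)) NA_integer_ else nrow(x$series)))
  invisible(x)
}

#' @export
coef.membrane_calibration <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
summary.membrane_calibration <- function(object, ...) {
  print(object)
  if (object$slope > 0 && object$intercept < 0.9)
    cat(sprintf("  apparent MWCO (90%% retention): %.4g g/mol\n",
                apparent_mwco(object)))
  if (!is.null(object$fit)) {
    cat("\nUnderlying regression of retention on log10(MW):\n")
    print(summary(object$fit))
  }
  invisible(object)
}

#' @param object,newdata `predict()` method arguments: a fitted
#'   calibration and the molar masses (g/mol) at which to evaluate it.
#' @rdname retention_at
#' @export
predict.membrane_calibration <- function(object, newdata, ...) {
  retention_at(object, newdata)
}

#' @export
plot.membrane_calibration <- function(x, ...) {
  if (!is.null(x$series)) {
    graphics::plot(log10(x$series$mw_gmol), x$series$retention,
                   xlab = "log10 MW (g/mol)", ylab = "retention R",
                   pch = 20, col = "grey40", ...)
  } else {
    rng <- x$fit_mw_window %||% c(220, 1890)
    graphics::plot(log10(rng), retention_at(x, rng), type = "n",
                   xlab = "log10 MW (g/mol)", ylab = "retention R",
                   ylim = c(0, 1), ...)
  }
  graphics::curve(pmin(1, pmax(0, x$slope * t + x$intercept)), xname = "t",
                  add = TRUE, col = "red3", lwd = 2)
  invisible(x)
}

#' Evaluate a membrane calibration
#'
#' Retention of a solute of molar mass `mw` under the linear sieving law,
#' clipped to the physical range:
#' `R = min(1, max(0, slope * log10(mw) + intercept))`.
#'
#' @param cal A [membrane_calibration()].
#' @param mw Molar masses in g/mol; positive.
#' @param ... Unused.
#' @return Retentions in `[0, 1]`, same length as `mw`.
#' @export
retention_at <- function(cal, mw) {
  stopifnot(inherits(cal, "membrane_calibration"))
  if (any(!is.finite(mw) | mw <= 0))
    stop("`mw` must be positive", call. = FALSE)
  pmin(1, pmax(0, cal$slope * log10(mw) + cal$intercept))
}

#' Apparent molecular-weight cut-off
#'
#' The molar mass of a solute retained at `level` (by convention 90%)
#' according to the fitted sieving law: `10^((level - intercept) / slope)`.
#' This apparent MWCO generally differs from the manufacturer's nominal
#' label, which is established with standards of different shape than
#' peptides.
#'
#' @param cal A [membrane_calibration()] with strictly positive slope.
#' @param level Retention level, strictly between `max(0, intercept)` and 1.
#' @return Molar mass in g/mol.
#' @export
apparent_mwco <- function(cal, level = 0.9) {
  stopifnot(inherits(cal, "membrane_calibration"))
  if (cal$slope <= 0)
    stop("apparent MWCO requires a strictly positive slope", call. = FALSE)
  if (!(level > max(0, cal$intercept) && level < 1))
    stop("`level` must lie strictly between max(0, intercept) and 1",
         call. = FALSE)
  10^((level - cal$intercept) / cal$slope)
}
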