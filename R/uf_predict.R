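#' Target peptide description
#'
#' Annotation of the peptide whose recovery is being predicted. Defaults
#' describe neokyotorphin (NKT), the antimicrobial alpha137-141 pentapeptide
#' of bovine hemoglobin (TSKYR, 653 g/mol), with the RP-HPLC response
#' coefficient linking its 214 nm peak area to concentration,
#' `C (mg/L) = 4419.6 * A (uV s)`.
#'
#' @param name Peptide name.
#' @param mw Molar mass in g/mol; positive.
#' @param rp_area_coefficient RP-HPLC response coefficient in mg/L per
#'   uV s; positive.
#' @param initial_purity Mass purity of the peptide in the starting
#'   hydrolysate, in percent (optional).
#' @return An object of class `"target_peptide"`.
#' @export
target_peptide <- function(name = "neokyotorphin", mw = 653,
                           rp_area_coefficient = 4419.6,
                           initial_purity = NULL) {
  if (!is.numeric(mw) || length(mw) != 1L || mw <= 0)
    stop("`mw` must be a positive scalar", call. = FALSE)
  if (rp_area_coefficient <= 0)
    stop("`rp_area_coefficient` must be positive", call. = FALSE)
  if (!is.null(initial_purity) &&
      (initial_purity <= 0 || initial_purity > 100))
    stop("`initial_purity` must be in (0, 100] percent", call. = FALSE)
  structure(list(name = as.character(name), mw = as.numeric(mw),
                 rp_area_coefficient = as.numeric(rp_area_coefficient),
                 initial_purity = initial_purity),
            class = "target_peptide")
}

#' Batch-UF mass balance: relative permeate concentration and yield
#'
#' For a batch concentration run at constant observed retention `R`, the
#' cumulative (volume-averaged) concentration of a solute in the permeate
#' compartment, relative to its feed concentration, is
#' `C_p/C_0 = (VRF - VRF^R) / (VRF - 1)`, with the analytic limit `1 - R`
#' at `VRF = 1` (the branch switches at `|VRF - 1| < 1e-9`). The yield is
#' the permeate-compartment mass fraction
#' `eta = C_p/C_0 * (1 - 1/VRF)`, algebraically equal to
#' `1 - VRF^(R - 1)`.
#'
#' @param R Observed retentions in `[0, 1]`.
#' @param vrf Volume reduction factors `V_0 / V_R`, at least 1.
#' @return A numeric vector (recycled over `R` and `vrf`):
#'   `relative_permeate_concentration()` returns `C_p/C_0` in `[0, 1]`;
#'   `species_yield()` returns the yield in `[0, 1]`.
#' @examples
#' relative_permeate_concentration(0.305, 3)   # 0.801
#' species_yield(0.625, 5)                     # 0.453
#' @export
relative_permeate_concentration <- function(R, vrf) {
  if (any(!is.finite(R) | R < 0 | R > 1))
    stop("`R` must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(vrf) | vrf < 1))
    stop("`vrf` must be >= 1", call. = FALSE)
  n <- max(length(R), length(vrf))
  R <- rep_len(R, n)
  vrf <- rep_len(vrf, n)
  out <- numeric(n)
  lim <- abs(vrf - 1) < 1e-9
  out[lim] <- 1 - R[lim]
  out[!lim] <- (vrf[!lim] - vrf[!lim]^R[!lim]) / (vrf[!lim] - 1)
  out
}

#' @rdname relative_permeate_concentration
#' @export
species_yield <- function(R, vrf) {
  relative_permeate_concentration(R, vrf) * (1 - 1 / vrf)
}

#' Predict the permeate-compartment profile at a given VRF
#'
#' Applies the batch mass balance pointwise: each point of the hydrolysate
#' profile is assigned a retention from the membrane calibration through
#' its molar mass, and its permeate-compartment concentration is
#' `C_0,x * (VRF - VRF^R_x) / (VRF - 1)`. The per-point retentions come
#' from the calibration, never from reused experimental ratios. The
#' returned profile integrates to the total permeate-compartment
#' concentration at that VRF.
#'
#' @param profile A [hydrolysate_profile()] of the feed.
#' @param cal A [membrane_calibration()].
#' @param vrf A single volume reduction factor, at least 1.
#' @return A [hydrolysate_profile()] of the permeate compartment on the
#'   same grid, with a `"vrf"` attribute.
#' @export
predict_permeate_profile <- function(profile, cal, vrf) {
  stopifnot(inherits(profile, "hydrolysate_profile"),
            inherits(cal, "membrane_calibration"),
            length(vrf) == 1L)
  R <- retention_at(cal, profile$mw)
  perm <- hydrolysate_profile(
    profile$mw,
    profile$concentration * relative_permeate_concentration(R, vrf),
    time = profile$time, target = profile$target,
    label = if (nzchar(profile$label))
      paste0(profile$label, " (permeate, VRF ", format(vrf), ")") else "")
  attr(perm, "vrf") <- vrf
  perm
}

#' Enrichment of the target peptide in the permeate compartment
#'
#' `tau = (C_p,target / C_0,target) * (sum C_0 / sum C_p)`: the target's
#' own transmission ratio (scalar mass balance at the retention of its
#' molar mass) times the inverse of the total peptide transmission ratio
#' (integral of the predicted permeate profile over the integral of the
#' feed profile). The permeate purity is `initial purity * tau`.
#'
#' @param profile A [hydrolysate_profile()] of the feed; the target molar
#'   mass must lie inside its molar-mass support.
#' @param cal A [membrane_calibration()].
#' @param target A [target_peptide()].
#' @param vrf A single volume reduction factor, at least 1.
#' @return The enrichment factor `tau` (dimensionless, positive).
#' @export
enrichment <- function(profile, cal, target, vrf) {
  stopifnot(inherits(profile, "hydrolysate_profile"),
            inherits(cal, "membrane_calibration"),
            inherits(target, "target_peptide"))
  if (target$mw < min(profile$mw) || target$mw > max(profile$mw))
    stop("target molar mass lies outside the profile's molar-mass support",
         call. = FALSE)
  perm <- predict_permeate_profile(profile, cal, vrf)
  if (perm$total_concentration <= 0)
    stop("predicted permeate concentration is zero: enrichment undefined",
         call. = FALSE)
  rel_target <- relative_permeate_concentration(retention_at(cal, target$mw),
                                                vrf)
  rel_target * profile$total_concentration / perm$total_concentration
}

#' Permeate purity from initial purity and enrichment
#'
#' `purity = initial_purity * tau`, capped at 100% with a warning (the
#' mass-balance product can numerically exceed 100% on a coarse profile).
#'
#' @param initial_purity Purity of the target in the feed, percent;
#'   positive.
#' @param tau Enrichment factor; positive.
#' @return Permeate purity in percent.
#' @export
permeate_purity <- function(initial_purity, tau) {
  if (any(initial_purity <= 0) || any(tau <= 0))
    stop("inputs must be positive", call. = FALSE)
  p <- initial_purity * tau
  if (any(p > 100)) {
    warning("computed purity exceeds 100%; capped", call. = FALSE)
    p <- pmin(p, 100)
  }
  p
}

#' Target concentration and purity from RP-HPLC peak areas
#'
#' `concentration_from_area()` applies the linear response
#' `C = coefficient * area` (mg/L). `purity_from_areas()` is the target
#' peak area over the total peptide area, times 100.
#'
#' @param area Target peak area in uV s; non-negative.
#' @param target A [target_peptide()] carrying the response coefficient.
#' @param a_target,a_total Target and total peak areas in uV s;
#'   `a_total` must be positive and at least `a_target`.
#' @return mg/L for `concentration_from_area()`; percent for
#'   `purity_from_areas()`.
#' @export
concentration_from_area <- function(area, target = target_peptide()) {
  stopifnot(inherits(target, "target_peptide"))
  if (any(area < 0)) stop("`area` must be non-negative", call. = FALSE)
  target$rp_area_coefficient * area
}

#' @rdname concentration_from_area
#' @export
purity_from_areas <- function(a_target, a_total) {
  if (any(a_target < 0) || any(a_total <= 0))
    stop("areas must be non-negative with a positive total", call. = FALSE)
  if (any(a_target > a_total))
    stop("target area exceeds total area", call. = FALSE)
  a_target / a_total * 100
}

#' Volume reduction factor achieving a target yield
#'
#' Inverts the closed-form yield `eta = 1 - VRF^(R - 1)` at the retention
#' of the target's molar mass: `VRF = (1 - yield_goal)^(1 / (R - 1))`.
#'
#' @param cal A [membrane_calibration()].
#' @param target A [target_peptide()].
#' @param yield_goal Desired yield, strictly between 0 and 1.
#' @return The VRF at which the target reaches `yield_goal`.
#' @export
vrf_for_yield <- function(cal, target, yield_goal) {
  stopifnot(inherits(cal, "membrane_calibration"),
            inherits(target, "target_peptide"))
  if (!(yield_goal > 0 && yield_goal < 1))
    stop("`yield_goal` must lie strictly between 0 and 1", call. = FALSE)
  R <- retention_at(cal, target$mw)
  if (R >= 1)
    stop("target is fully retained (R = 1): the yield goal is unreachable",
         call. = FALSE)
  (1 - yield_goal)^(1 / (R - 1))
}

#' Sweep the prediction over a VRF grid
#'
#' Assembles the target yield, enrichment, permeate purity and total
#' permeate-compartment concentration over a grid of volume reduction
#' factors. The default grid covers 1.1 to 10 with 90 log-spaced points.
#'
#' @param profile A [hydrolysate_profile()] of the feed.
#' @param cal A [membrane_calibration()].
#' @param target A [target_peptide()].
#' @param vrf Increasing grid of volume reduction factors, each at least 1.
#' @param initial_purity Feed purity of the target in percent; defaults to
#'   the target's own annotation. When unknown the purity column is `NA`.
#' @return A data frame of class `"uf_prediction"` with columns `vrf`,
#'   `yield`, `rel_conc_target`, `sum_cp_gL`, `enrichment`, `purity_pct`.
#' @export
vrf_sweep <- function(profile, cal, target,
                      vrf = 10^seq(log10(1.1), 1, length.out = 90L),
                      initial_purity = NULL) {
  stopifnot(inherits(profile, "hydrolysate_profile"),
            inherits(cal, "membrane_calibration"),
            inherits(target, "target_peptide"))
  if (any(vrf < 1) || is.unsorted(vrf, strictly = TRUE))
    stop("`vrf` must be an increasing grid with values >= 1", call. = FALSE)
  initial_purity <- initial_purity %||% target$initial_purity
  R_target <- retention_at(cal, target$mw)
  R_x <- retention_at(cal, profile$mw)
  w <- if (is.null(profile$time)) rep(1, length(profile$mw))
       else trapezoid_weights(profile$time)
  sum_c0 <- profile$total_concentration
  rows <- lapply(vrf, function(v) {
    rel_x <- relative_permeate_concentration(R_x, v)
    sum_cp <- sum(profile$concentration * rel_x * w)
    rel_t <- relative_permeate_concentration(R_target, v)
    tau <- if (sum_cp > 0) rel_t * sum_c0 / sum_cp else NA_real_
    data.frame(vrf = v,
               yield = rel_t * (1 - 1 / v),
               rel_conc_target = rel_t,
               sum_cp_gL = sum_cp,
               enrichment = tau)
  })
  out <- do.call(rbind, rows)
  out$purity_pct <- if (is.null(initial_purity)) NA_real_
                    else permeate_purity(initial_purity, out$enrichment)
  class(out) <- c("uf_prediction", "data.frame")
  attr(out, "target") <- target
  attr(out, "calibration") <- coef(cal)
  attr(out, "initial_purity") <- initial_purity
  out
}

#' @export
print.uf_prediction <- function(x, ...) {
  tgt <- attr(x, "target")
  cat(sprintf("UF prediction for %s (%g g/mol) over VRF %.3g-%.3g (%d points)\n",
              tgt$name, tgt$mw, min(x$vrf), max(x$vrf), nrow(x)))
  show <- x[unique(round(seq(1L, nrow(x), length.out = min(6L, nrow(x))))), ]
  print.data.frame(show, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.uf_prediction <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$vrf, x$yield, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "VRF", ylab = "target yield", ...)
  graphics::plot(x$vrf, x$enrichment, type = "l", lwd = 2,
                 xlab = "VRF", ylab = "target enrichment", ...)
  invisible(x)
}

#' Process productivity
#'
#' Permeate peptide mass per membrane area per time, in g/m2/h.
#'
#' @param permeate_mass Peptide mass recovered in the permeate, g.
#' @param area Membrane area, m2.
#' @param duration Filtration duration, h.
#' @return Productivity in g/m2/h.
#' @export
productivity <- function(permeate_mass, area, duration) {
  if (any(permeate_mass < 0) || any(area <= 0) || any(duration <= 0))
    stop("`permeate_mass` must be non-negative and `area`, `duration` positive",
         call. = FALSE)
  permeate_mass / (area * duration)
}
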