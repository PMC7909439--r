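#' Specification of a synthetic hydrolysate chromatogram
#'
#' Describes a seeded synthetic peptide mixture rendered as a
#' size-exclusion chromatogram. Molar masses are drawn from a mixture of
#' log-normal components (emulating the bimodal intermediate/final peptide
#' population of a zipper-type proteolysis, whose balance shifts with the
#' degree of hydrolysis); an optional target species is pinned at an exact
#' molar mass with an exact mass fraction. Each species is rendered as a
#' Gaussian elution peak centred at the inverse column-calibration time,
#' with amplitude from the inverse of the per-residue absorbance
#' conversion, so the chromatogram's integrated concentration recovers the
#' species masses.
#'
#' @param components List of mixture components, each a list with fields
#'   `median` (g/mol), `log_sd` (standard deviation on the natural-log
#'   scale), `weight` (mass weight; weights must sum to 1) and optionally
#'   `range` (sampling window in g/mol; draws outside are rejected and
#'   resampled).
#' @param n_species Number of non-target species to sample.
#' @param target_mass_fraction Mass fraction of the target species, in
#'   `[0, 1)`.
#' @param target_mw Molar mass of the target species, g/mol.
#' @param peak_sigma Gaussian elution-peak width, minutes.
#' @param noise_sd Additive detector noise, as a fraction of the maximum
#'   signal.
#' @param seed Integer seed; all randomness flows from it.
#' @param total_concentration Total peptide concentration, g/L.
#' @param mw_hard_range Hard molar-mass window; sampling outside it is
#'   rejected.
#' @param time_step Chromatogram grid step, minutes.
#' @param label Free text.
#' @return An object of class `"synthetic_hydrolysate_spec"`.
#' @seealso [dh_preset()], [generate_hydrolysate()]
#' @export
synthetic_hydrolysate_spec <- function(components,
                                       n_species = 120L,
                                       target_mass_fraction = 0.025,
                                       target_mw = 653,
                                       peak_sigma = 0.25,
                                       noise_sd = 0,
                                       seed = 1L,
                                       total_concentration = 10,
                                       mw_hard_range = c(150, 2e4),
                                       time_step = 0.02,
                                       label = "synthetic hydrolysate") {
  stopifnot(is.list(components), length(components) >= 1L)
  for (cmp in components) {
    if (!all(c("median", "log_sd", "weight") %in% names(cmp)))
      stop("each component needs `median`, `log_sd` and `weight`",
           call. = FALSE)
    if (cmp$median <= 0 || cmp$log_sd <= 0 || cmp$weight <= 0)
      stop("component scales and weights must be positive", call. = FALSE)
  }
  w <- vapply(components, `[[`, numeric(1L), "weight")
  if (abs(sum(w) - 1) > 1e-8)
    stop("component weights must sum to 1", call. = FALSE)
  if (!(target_mass_fraction >= 0 && target_mass_fraction < 1))
    stop("`target_mass_fraction` must lie in [0, 1)", call. = FALSE)
  if (peak_sigma <= 0 || total_concentration <= 0 || time_step <= 0)
    stop("scales must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(components = components, n_species = as.integer(n_species),
                 target_mass_fraction = target_mass_fraction,
                 target_mw = target_mw, peak_sigma = peak_sigma,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 total_concentration = total_concentration,
                 mw_hard_range = as.numeric(mw_hard_range),
                 time_step = time_step, label = label),
            class = "synthetic_hydrolysate_spec")
}

#' Preset synthetic hydrolysates at different degrees of hydrolysis
#'
#' Fixture mixtures emulating pepsin hydrolysates of bovine hemoglobin at
#' increasing degree of hydrolysis (DH): the mass balance shifts from a
#' high-molar-mass intermediate component towards a low-molar-mass final
#' component, the median molar mass falls from roughly 4000 ("3dh-col")
#' and 2600 ("3dh-dec") towards 1000 g/mol ("18dh"), and the target mass
#' fraction (initial purity) rises from 2.5% to 6.4%. These are
#' statistical stand-ins chosen once for testing, not reconstructions of
#' any measured chromatogram.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [synthetic_hydrolysate_spec()]
#'   (typically `seed` and `noise_sd`).
#' @return A `"synthetic_hydrolysate_spec"`.
#' @export
dh_preset <- function(name = c("3dh-col", "3dh-dec", "5dh", "10dh", "18dh"),
                      ...) {
  name <- match.arg(name)
  p <- switch(name,
    "3dh-col" = list(
      components = list(
        list(median = 4000, log_sd = 0.50, weight = 0.99,
             range = c(700, 20000)),
        list(median = 450, log_sd = 0.25, weight = 0.01,
             range = c(200, 640))),
      target_mass_fraction = 0.025),
    "3dh-dec" = list(
      components = list(
        list(median = 2800, log_sd = 0.50, weight = 0.9723,
             range = c(700, 20000)),
        list(median = 480, log_sd = 0.25, weight = 0.0277,
             range = c(200, 640))),
      target_mass_fraction = 0.026),
    "5dh" = list(
      components = list(
        list(median = 2000, log_sd = 0.50, weight = 0.92,
             range = c(700, 15000)),
        list(median = 520, log_sd = 0.30, weight = 0.08,
             range = c(200, 645))),
      target_mass_fraction = 0.045),
    "10dh" = list(
      components = list(
        list(median = 1500, log_sd = 0.55, weight = 0.82,
             range = c(660, 12000)),
        list(median = 560, log_sd = 0.35, weight = 0.18,
             range = c(200, 645))),
      target_mass_fraction = 0.055),
    "18dh" = list(
      components = list(
        list(median = 1200, log_sd = 0.60, weight = 0.70,
             range = c(660, 10000)),
        list(median = 600, log_sd = 0.40, weight = 0.30,
             range = c(200, 645))),
      target_mass_fraction = 0.064))
  args <- utils::modifyList(
    c(p, list(label = paste0("synthetic ", name, " hydrolysate"))),
    list(...))
  do.call(synthetic_hydrolysate_spec, args)
}

#' Generate a synthetic hydrolysate chromatogram with its ground truth
#'
#' Samples the species of `spec`, renders them as Gaussian elution peaks
#' on the column-calibration time grid, adds detector noise, and returns
#' both the chromatogram and the exact species list used to build it. The
#' output is bit-identical for a given spec (the global RNG state is left
#' untouched).
#'
#' @param spec A [synthetic_hydrolysate_spec()].
#' @param column_cal A [column_calibration()] (its inverse places the
#'   peaks).
#' @param ref A [protein_reference()] (its inverse sets the amplitudes).
#' @param max_attempts Rejection-sampling cap per species; exceeding it is
#'   an error.
#' @return A list with elements `chromatogram` (a [chromatogram()]) and
#'   `truth` (class `"synthetic_truth"`: the species data frame with
#'   columns `mw`, `mass`, `retention_time`, `is_target`, plus the spec).
#' @export
generate_hydrolysate <- function(spec, column_cal = column_calibration(),
                                 ref = protein_reference(),
                                 max_attempts = 1000L) {
  stopifnot(inherits(spec, "synthetic_hydrolysate_spec"),
            inherits(column_cal, "column_calibration"),
            inherits(ref, "protein_reference"))
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(spec$seed)

  comps <- spec$components
  weights <- vapply(comps, `[[`, numeric(1L), "weight")
  n_per <- pmax(1L, round(spec$n_species * weights))
  mw <- numeric(0)
  mass <- numeric(0)
  non_target_total <- (1 - spec$target_mass_fraction) * spec$total_concentration
  for (j in seq_along(comps)) {
    rng <- comps[[j]]$range %||% spec$mw_hard_range
    rng <- c(max(rng[1L], spec$mw_hard_range[1L]),
             min(rng[2L], spec$mw_hard_range[2L]))
    m <- numeric(n_per[j])
    for (i in seq_len(n_per[j])) {
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        x <- stats::rlnorm(1L, meanlog = log(comps[[j]]$median),
                           sdlog = comps[[j]]$log_sd)
        if (x >= rng[1L] && x <= rng[2L]) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf("could not sample a molar mass in [%g, %g] after %d attempts",
                     rng[1L], rng[2L], max_attempts), call. = FALSE)
      m[i] <- x
    }
    # exact per-component mass allocation: component weights are realised
    # exactly, the split inside a component is random
    g <- stats::rgamma(n_per[j], shape = 6, rate = 6)
    mw <- c(mw, m)
    mass <- c(mass, weights[j] * non_target_total * g / sum(g))
  }
  is_target <- rep(FALSE, length(mw))
  if (spec$target_mass_fraction > 0) {
    mw <- c(mw, spec$target_mw)
    mass <- c(mass, spec$target_mass_fraction * spec$total_concentration)
    is_target <- c(is_target, TRUE)
  }

  tr <- time_at_mw(column_cal, mw)
  t0 <- time_at_mw(column_cal, spec$mw_hard_range[2L]) - 4 * spec$peak_sigma
  t1 <- time_at_mw(column_cal, spec$mw_hard_range[1L]) + 4 * spec$peak_sigma
  times <- seq(t0, t1, by = spec$time_step)
  k <- ref$mean_residue_mass / ref$mean_residue_extinction  # 1 cm path
  a <- numeric(length(times))
  for (i in seq_along(mw))
    a <- a + (mass[i] * k^-1) * stats::dnorm(times, tr[i], spec$peak_sigma)
  if (spec$noise_sd > 0)
    a <- a + stats::rnorm(length(a), 0, spec$noise_sd * max(a))

  truth <- structure(
    list(species = data.frame(mw = mw, mass = mass, retention_time = tr,
                              is_target = is_target),
         spec = spec),
    class = "synthetic_truth")
  list(chromatogram = chromatogram(times, a, label = spec$label),
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d species, total %g g/L, target fraction %g\n",
              nrow(x$species), sum(x$species$mass),
              x$spec$target_mass_fraction))
  invisible(x)
}

#' Ground-truth initial purity of a synthetic hydrolysate
#' @param truth A `"synthetic_truth"` object.
#' @return Target mass fraction in percent.
#' @export
truth_initial_purity <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  100 * sum(truth$species$mass[truth$species$is_target]) /
    sum(truth$species$mass)
}

#' Generate a total-recirculation permeate/retentate pair
#'
#' Emulates the membrane-calibration experiment: the retentate trace is
#' the feed chromatogram, and the permeate trace is the feed attenuated
#' pointwise by the true transmission `1 - R(MW)` of a known sieving law.
#' Multiplicative Gaussian noise of relative standard deviation `noise_sd`
#' is applied independently to both traces (noise lives in the absorbance
#' domain, where the retention ratio is formed).
#'
#' @param chrom Feed [chromatogram()].
#' @param true_cal The [membrane_calibration()] to imprint.
#' @param column_cal The [column_calibration()] mapping times to molar
#'   masses.
#' @param noise_sd Relative noise standard deviation (0 for none).
#' @param seed Integer seed.
#' @return A list with elements `retentate` and `permeate`
#'   ([chromatogram()]s on the feed grid).
#' @export
generate_recycle_pair <- function(chrom, true_cal,
                                  column_cal = column_calibration(),
                                  noise_sd = 0, seed = 1L) {
  stopifnot(inherits(chrom, "chromatogram"),
            inherits(true_cal, "membrane_calibration"),
            inherits(column_cal, "column_calibration"))
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(seed)
  mw <- as.numeric(mw_at_time(column_cal, chrom$time))
  transmission <- 1 - retention_at(true_cal, mw)
  n <- length(chrom$time)
  noisy <- function(a) {
    if (noise_sd > 0) a * (1 + stats::rnorm(n, 0, noise_sd)) else a
  }
  list(
    retentate = chromatogram(chrom$time, noisy(chrom$absorbance),
                             wavelength = chrom$wavelength,
                             path_length = chrom$path_length,
                             label = paste(chrom$label, "(retentate)")),
    permeate = chromatogram(chrom$time, noisy(chrom$absorbance * transmission),
                            wavelength = chrom$wavelength,
                            path_length = chrom$path_length,
                            label = paste(chrom$label, "(permeate)")))
}

#' Brute-force batch ultrafiltration oracle
#'
#' Simulates a batch concentration run by removing the permeate volume in
#' `n_steps` equal increments. At each step every species loses mass at
#' its instantaneous sieving rate, `(1 - R) * c_retentate * dV`, and the
#' removed mass accumulates in the permeate compartment. This explicit
#' forward volume stepping is deliberately naive and auditable; it serves
#' as an independent numerical check of the closed-form mass balance.
#'
#' @param retention Per-species retentions in `[0, 1]`.
#' @param vrf Final volume reduction factor, strictly greater than 1.
#' @param n_steps Number of volume increments (at least 10; use 1e5 for
#'   1e-4-level agreement with the closed form).
#' @param v0 Initial volume (L); results are reported relative to the feed
#'   so the default 1 is only a bookkeeping scale.
#' @param c0 Feed concentration of each species (recycled).
#' @return A data frame with one row per species: `retention`, `yield`,
#'   `rel_permeate_conc` (volume-averaged permeate concentration over
#'   feed), `rel_retentate_conc` (final retentate concentration over
#'   feed).
#' @export
batch_oracle <- function(retention, vrf, n_steps = 1e5, v0 = 1, c0 = 1) {
  if (any(!is.finite(retention) | retention < 0 | retention > 1))
    stop("`retention` must lie in [0, 1]", call. = FALSE)
  if (!(length(vrf) == 1L && is.finite(vrf) && vrf > 1))
    stop("`vrf` must be a single value > 1", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (n_steps < 10L) stop("`n_steps` must be at least 10", call. = FALSE)
  c0 <- rep_len(c0, length(retention))
  v_final <- v0 / vrf
  dv <- (v0 - v_final) / n_steps
  yield <- numeric(length(retention))
  rel_p <- numeric(length(retention))
  rel_r <- numeric(length(retention))
  for (s in seq_along(retention)) {
    transmit <- 1 - retention[s]
    m <- c0[s] * v0
    mp <- 0
    v <- v0
    for (k in seq_len(n_steps)) {
      dm <- transmit * (m / v) * dv
      m <- m - dm
      mp <- mp + dm
      v <- v - dv
    }
    yield[s] <- mp / (c0[s] * v0)
    rel_p[s] <- (mp / (v0 - v_final)) / c0[s]
    rel_r[s] <- (m / v_final) / c0[s]
  }
  data.frame(retention = retention, yield = yield,
             rel_permeate_conc = rel_p, rel_retentate_conc = rel_r)
}
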