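# Shared fixtures: the two published regenerated-cellulose membrane
# calibration lines and convenience generators.

cal_1k <- function() membrane_calibration(0.7978, -1.6206, mwco_nominal = 1000)
cal_3k <- function() membrane_calibration(1.0552, -2.666, mwco_nominal = 3000)

sec_column <- function() column_calibration()

# A hydrolysate confined to a molar-mass window where the 1 kg/mol sieving
# law stays strictly inside (0, 1): recycle pairs built from it carry the
# unclipped linear law at every retained point.
calibration_fixture <- function(seed = 1, noise_sd = 0, n_species = 60L) {
  synthetic_hydrolysate_spec(
    components = list(
      list(median = 1200, log_sd = 0.45, weight = 0.9, range = c(300, 1600)),
      list(median = 500, log_sd = 0.30, weight = 0.1, range = c(300, 1600))),
    n_species = n_species, target_mass_fraction = 0,
    noise_sd = noise_sd, seed = seed,
    mw_hard_range = c(250, 1890), time_step = 0.02,
    label = "calibration fixture")
}

# Feed with exactly 2.7% of its mass strictly below the 653 g/mol target,
# and a clear gap around 653 so peak broadening cannot move mass across
# the threshold.
gapped_fixture <- function(seed = 1) {
  synthetic_hydrolysate_spec(
    components = list(
      list(median = 450, log_sd = 0.25, weight = 0.027, range = c(200, 560)),
      list(median = 2600, log_sd = 0.45, weight = 0.973, range = c(760, 8000))),
    n_species = 100L, target_mass_fraction = 0, seed = seed,
    label = "gapped fixture")
}

# Discrete species profile helper (point masses, no time grid).
species_profile <- function(mw, mass, target = NULL) {
  hydrolysate_profile(mw, mass, target = target)
}
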