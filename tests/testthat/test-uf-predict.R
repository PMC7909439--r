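test_that("the batch mass balance has the right limits and values", {
  # fully transmitted / fully retained solutes
  expect_equal(relative_permeate_concentration(0, c(1, 2, 5, 50)),
               rep(1, 4))
  expect_equal(relative_permeate_concentration(1, c(1, 2, 5, 50)),
               rep(0, 4))
  # direct evaluation at the 3 kg/mol target retention
  expect_lt(abs(relative_permeate_concentration(0.305, 3) - 0.801), 5e-4)
  # vrf -> 1 limit agrees with the implemented limit branch
  R <- seq(0, 1, by = 0.1)
  expect_equal(relative_permeate_concentration(R, 1 + 1e-8),
               relative_permeate_concentration(R, 1), tolerance = 1e-6)
  expect_error(relative_permeate_concentration(1.2, 3), "\\[0, 1\\]")
  expect_error(relative_permeate_concentration(0.5, 0.9), ">= 1")
})

test_that("yield equals the closed form 1 - vrf^(R-1) to machine precision", {
  R <- seq(0, 1, length.out = 10)
  vrf <- seq(1.1, 10, length.out = 10)
  for (v in vrf)
    expect_equal(species_yield(R, v), 1 - v^(R - 1), tolerance = 1e-14)
  # published anchor points
  expect_lt(abs(species_yield(0.625, 5) - 0.453), 1e-3)
  expect_equal(species_yield(0, 5), 1 - 1 / 5, tolerance = 1e-14)
})

test_that("yield is monotone in vrf and retention, and mass is conserved", {
  vrf <- 10^seq(log10(1.1), 1, length.out = 40)
  for (R in c(0, 0.3, 0.625, 0.9)) {
    y <- species_yield(R, vrf)
    expect_true(all(diff(y) > 0))  # strictly increasing in vrf for R < 1
  }
  R <- seq(0, 1, length.out = 40)
  for (v in c(1.5, 3, 5, 10))
    expect_true(all(diff(species_yield(R, v)) < 0))  # decreasing in R
  # per-species mass conservation: permeate + retentate = feed
  grid <- expand.grid(R = seq(0, 1, by = 0.125), vrf = c(1.1, 2, 3, 5, 10))
  permeate_mass <- relative_permeate_concentration(grid$R, grid$vrf) *
    (1 - 1 / grid$vrf)
  retentate_mass <- grid$vrf^grid$R / grid$vrf
  expect_equal(permeate_mass + retentate_mass, rep(1, nrow(grid)),
               tolerance = 1e-9)
})

test_that("the brute-force batch oracle agrees with the closed form", {
  for (R in c(0, 0.3, 0.625, 0.9, 1)) {
    for (vrf in c(1.1, 3, 5, 10)) {
      o <- batch_oracle(R, vrf, n_steps = 1e5)
      expect_lt(abs(o$yield - (1 - vrf^(R - 1))),
                1e-4 * max(1, abs(1 - vrf^(R - 1))))
      expect_lt(abs(o$rel_permeate_conc -
                    relative_permeate_concentration(R, vrf)), 2e-4)
      # oracle bookkeeping is exactly conservative
      expect_equal(o$yield + o$rel_retentate_conc / vrf, 1, tolerance = 1e-9)
    }
  }
  expect_equal(batch_oracle(1, 5, 1e3)$yield, 0)
  expect_error(batch_oracle(0.5, 1), "> 1")
})

test_that("oracle error decreases monotonically with step count", {
  for (R in c(0.3, 0.625, 0.9)) {
    for (vrf in c(3, 10)) {
      err <- vapply(c(1e3, 1e4, 1e5), function(n)
        abs(batch_oracle(R, vrf, n)$yield - (1 - vrf^(R - 1))), numeric(1))
      expect_true(all(diff(err) < 0))
    }
  }
})

test_that("permeate profile prediction reduces to the scalar mass balance", {
  # idealised fully transmitting membrane: permeate equals feed
  open_cal <- membrane_calibration(0, 0)
  gen <- generate_hydrolysate(dh_preset("5dh", seed = 9))
  prof <- absorbance_to_concentration(gen$chromatogram, sec_column())
  perm <- predict_permeate_profile(prof, open_cal, 5)
  expect_equal(perm$concentration, prof$concentration, tolerance = 1e-12)
  # single species: total is C0 times the scalar mass-balance factor
  one <- species_profile(1000, 3)
  p1 <- predict_permeate_profile(one, cal_1k(), 4)
  expect_equal(p1$total_concentration,
               3 * relative_permeate_concentration(retention_at(cal_1k(), 1000), 4),
               tolerance = 1e-12)
  # per-point agreement with the independent batch simulation
  sp <- species_profile(c(400, 653, 1000, 1500, 2500), c(1, 0.5, 2, 3, 1))
  pred <- predict_permeate_profile(sp, cal_1k(), 5)
  o <- batch_oracle(retention_at(cal_1k(), sp$mw), 5, n_steps = 1e5,
                    c0 = sp$concentration)
  expect_equal(pred$concentration, o$rel_permeate_conc * sp$concentration,
               tolerance = 2e-4)
})

test_that("enrichment follows the two-ratio definition", {
  tgt <- target_peptide()
  # all species share the target molar mass: no enrichment possible
  uniform <- species_profile(rep(653, 4), c(1, 2, 3, 4))
  expect_equal(enrichment(uniform, cal_1k(), tgt, 5), 1, tolerance = 1e-12)
  # all non-target mass fully retained: maximal enrichment sum(C0)/C0_target
  blocked <- species_profile(c(653, 5000, 8000), c(0.5, 6, 3.5))
  expect_equal(enrichment(blocked, cal_1k(), tgt, 5), 10 / 0.5,
               tolerance = 1e-12)
  # target outside the profile support is rejected
  expect_error(enrichment(species_profile(c(1000, 2000), c(1, 1)),
                          cal_1k(), tgt, 5), "support")
  # fully retaining membrane: no permeate, enrichment undefined
  tight <- membrane_calibration(1, 0)
  expect_error(enrichment(uniform, tight, tgt, 5), "zero")
})

test_that("purity propagates as initial purity times enrichment", {
  expect_equal(permeate_purity(2.6, 10.7), 27.82, tolerance = 1e-12)
  expect_equal(permeate_purity(5, 1), 5)
  expect_warning(p <- permeate_purity(20, 6), "capped")
  expect_equal(p, 100)
  expect_error(permeate_purity(-1, 2), "positive")
})

test_that("RP-HPLC area conversions are linear", {
  expect_equal(concentration_from_area(0.01), 44.196)
  expect_equal(concentration_from_area(0), 0)
  expect_equal(purity_from_areas(0.3, 0.3), 100)
  expect_equal(purity_from_areas(0, 0.3), 0)
  expect_error(purity_from_areas(0.4, 0.3), "exceeds")
})

test_that("vrf_for_yield inverts the yield curve", {
  tgt <- target_peptide()
  # inverse of the forward yield at the published retentions
  y5 <- species_yield(retention_at(cal_1k(), 653), 5)
  expect_equal(vrf_for_yield(cal_1k(), tgt, y5), 5, tolerance = 1e-9)
  y3 <- species_yield(retention_at(cal_3k(), 653), 3)
  expect_equal(vrf_for_yield(cal_3k(), tgt, y3), 3, tolerance = 1e-9)
  # independent root-finding cross-check
  R <- retention_at(cal_1k(), 653)
  root <- uniroot(function(v) 1 - v^(R - 1) - 0.6, c(1 + 1e-9, 1e6),
                  tol = 1e-12)$root
  expect_equal(vrf_for_yield(cal_1k(), tgt, 0.6), root, tolerance = 1e-8)
  # small goals need vrf barely above 1
  expect_lt(vrf_for_yield(cal_1k(), tgt, 1e-6), 1 + 1e-4)
  # unreachable when the target is fully retained
  heavy <- target_peptide(mw = 1e6)
  expect_error(vrf_for_yield(cal_1k(), heavy, 0.5), "unreachable")
})

test_that("vrf_sweep assembles consistent curves", {
  gen <- generate_hydrolysate(dh_preset("3dh-dec", seed = 21))
  prof <- absorbance_to_concentration(gen$chromatogram, sec_column())
  tgt <- target_peptide(initial_purity = truth_initial_purity(gen$truth))
  sw <- vrf_sweep(prof, cal_1k(), tgt)
  expect_s3_class(sw, "uf_prediction")
  expect_equal(nrow(sw), 90L)
  expect_true(all(diff(sw$yield) > 0))
  expect_true(all(sw$yield >= 0 & sw$yield <= 1))
  expect_true(all(sw$enrichment > 0))
  expect_true(all(sw$purity_pct >= 0 & sw$purity_pct <= 100))
  # a length-1 grid reduces to the scalar operations
  sw5 <- vrf_sweep(prof, cal_1k(), tgt, vrf = 5)
  expect_equal(sw5$yield, species_yield(retention_at(cal_1k(), 653), 5))
  expect_equal(sw5$enrichment, enrichment(prof, cal_1k(), tgt, 5))
  # purity via the permeate composition equals initial purity times tau
  perm <- predict_permeate_profile(prof, cal_1k(), 5)
  c0_target <- tgt$initial_purity / 100 * prof$total_concentration
  purity_from_composition <- 100 * c0_target * sw5$rel_conc_target /
    perm$total_concentration
  expect_equal(purity_from_composition, sw5$purity_pct, tolerance = 1e-9)
  expect_error(vrf_sweep(prof, cal_1k(), tgt, vrf = c(5, 3)), "increasing")
})

test_that("enrichment falls with VRF for low-DH feeds and stays flat at high DH", {
  tgt <- target_peptide()
  grid <- c(1.1, 2, 3, 5, 10)
  gen_lo <- generate_hydrolysate(dh_preset("3dh-col", seed = 31))
  prof_lo <- absorbance_to_concentration(gen_lo$chromatogram, sec_column())
  tau_lo <- vrf_sweep(prof_lo, cal_1k(), tgt, vrf = grid)$enrichment
  # low DH: most mass is far larger than the target -> enrichment in the
  # tens, decreasing as retained species leak through at high VRF
  expect_gt(tau_lo[1], 10)
  expect_true(all(diff(tau_lo) < 0))
  gen_hi <- generate_hydrolysate(dh_preset("18dh", seed = 32))
  prof_hi <- absorbance_to_concentration(gen_hi$chromatogram, sec_column())
  tau_hi <- vrf_sweep(prof_hi, cal_1k(), tgt, vrf = grid)$enrichment
  # high DH: retentions cluster around the target's -> roughly constant
  expect_lt(max(tau_hi) / min(tau_hi), 1.3)
  expect_lt(tau_hi[1], tau_lo[1])
})

test_that("productivity is mass per area per time", {
  expect_equal(productivity(1, 1, 1), 1)
  # 8.6 mg over an 88 cm2 membrane in one hour
  expect_equal(productivity(0.0086, 88e-4, 1), 0.977, tolerance = 1e-3)
  expect_equal(productivity(2, 1, 2), productivity(2, 1, 1) / 2)
  expect_error(productivity(1, 0, 1), "positive")
})
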