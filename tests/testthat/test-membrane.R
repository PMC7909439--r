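make_pair <- function(a_p, a_r, t = seq_along(a_r)) {
  list(permeate = chromatogram(t, a_p), retentate = chromatogram(t, a_r))
}

test_that("pointwise retention is 1 - Ap/Ar with threshold exclusion", {
  col <- sec_column()
  pr <- make_pair(c(0.2, 0.5, 0.0, 0.001), c(0.8, 0.5, 0.4, 0.002),
                  t = c(25, 26, 27, 28))
  s <- pointwise_retention(pr$permeate, pr$retentate, col, threshold = 0.02)
  # the 4th point sits below 2% of the retentate maximum and is dropped
  expect_equal(nrow(s), 3L)
  expect_equal(s$retention, c(0.75, 0, 1))
  expect_equal(s$mw_gmol, as.numeric(mw_at_time(col, c(25, 26, 27))))
  # identical traces give zero retention everywhere
  pr2 <- make_pair(c(0.3, 0.6, 0.3), c(0.3, 0.6, 0.3), t = 25:27)
  s2 <- pointwise_retention(pr2$permeate, pr2$retentate, col)
  expect_true(all(s2$retention == 0))
  # all signal below threshold -> error
  expect_error(
    pointwise_retention(chromatogram(25:27, c(0, 0, 0.5)),
                        chromatogram(30:32, c(1, 1, 1)), col),
    "no points retained")
  # wavelength mismatch -> error
  expect_error(
    pointwise_retention(chromatogram(25:27, 1:3, wavelength = 280),
                        chromatogram(25:27, 1:3), col),
    "wavelength")
})

test_that("retention ratios are invariant to uniform absorbance rescaling", {
  gen <- generate_hydrolysate(calibration_fixture(seed = 2))
  pair <- generate_recycle_pair(gen$chromatogram, cal_1k(), sec_column())
  scaled <- lapply(pair, function(ch)
    chromatogram(ch$time, 3.7 * ch$absorbance))
  col <- sec_column()
  s1 <- pointwise_retention(pair$permeate, pair$retentate, col)
  s2 <- pointwise_retention(scaled$permeate, scaled$retentate, col)
  expect_equal(s2$retention, s1$retention, tolerance = 1e-12)
  f1 <- fit_membrane_calibration(s1)
  f2 <- fit_membrane_calibration(s2)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-12)
})

test_that("the sieving law is recovered from a noiseless recycle pair", {
  truth <- cal_1k()
  gen <- generate_hydrolysate(calibration_fixture(seed = 3))
  pair <- generate_recycle_pair(gen$chromatogram, truth, sec_column(),
                                noise_sd = 0)
  s <- pointwise_retention(pair$permeate, pair$retentate, sec_column())
  # pointwise: the imprinted law is reproduced exactly at retained points
  expect_equal(s$retention, retention_at(truth, s$mw_gmol), tolerance = 1e-12)
  fit <- fit_membrane_calibration(s)
  expect_lt(abs(fit$slope - truth$slope), 1e-9)
  expect_lt(abs(fit$intercept - truth$intercept), 1e-9)
})

test_that("fitting degrades gracefully and rejects degenerate input", {
  col <- sec_column()
  t3 <- time_at_mw(col, c(1500, 1000, 500))
  s <- pointwise_retention(chromatogram(t3, c(0.2, 0.4, 0.6)),
                           chromatogram(t3, c(1, 1, 1)), col)
  expect_error(fit_membrane_calibration(s[1:2, ]), "at least 3")
  same_t <- chromatogram(c(25, 25 + 1e-12, 25 + 2e-12), c(1, 1, 1))
  expect_error(
    fit_membrane_calibration(
      pointwise_retention(chromatogram(same_t$time, c(0.5, 0.5, 0.5)),
                          same_t, col)),
    "degenerate")
  # decreasing retention with MW cannot yield a sieving calibration
  s_dec <- pointwise_retention(chromatogram(t3, c(0.8, 0.5, 0.2)),
                               chromatogram(t3, c(1, 1, 1)), col)
  expect_error(fit_membrane_calibration(s_dec), "not positive")
})

test_that("calibration fitting is accurate and linear under realistic noise", {
  truth <- cal_1k()
  gen <- generate_hydrolysate(calibration_fixture(seed = 4))
  fits <- lapply(1:20, function(seed) {
    pair <- generate_recycle_pair(gen$chromatogram, truth, sec_column(),
                                  noise_sd = 0.01, seed = seed)
    s <- pointwise_retention(pair$permeate, pair$retentate, sec_column())
    fit_membrane_calibration(s, mw_window = c(220, 1890))
  })
  slopes <- vapply(fits, function(f) f$slope, numeric(1))
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  n_pts <- vapply(fits, function(f) nrow(f$series), numeric(1))
  expect_true(all(n_pts >= 400))
  # seed-averaged slope within +/-0.02 of the imprinted law
  expect_lt(abs(mean(slopes) - truth$slope), 0.02)
  # linearly regressable, as for the published calibration curves
  expect_true(all(r2 >= 0.988))
})

test_that("retention evaluation reproduces the published values and clips", {
  expect_lt(abs(retention_at(cal_1k(), 653) - 0.625), 0.005)
  expect_lt(abs(retention_at(cal_3k(), 653) - 0.305), 0.005)
  expect_identical(retention_at(cal_1k(), 1e6), 1)  # clipped above
  expect_identical(retention_at(cal_3k(), 100), 0)  # clipped below
  # non-decreasing in molar mass for any positive-slope calibration
  mw <- 10^seq(2, 5, length.out = 100)
  for (cal in list(cal_1k(), cal_3k(), membrane_calibration(0.3, -0.5)))
    expect_true(all(diff(retention_at(cal, mw)) >= 0))
  # predict() is the same evaluation
  expect_identical(predict(cal_1k(), c(653, 1000)),
                   retention_at(cal_1k(), c(653, 1000)))
  expect_error(retention_at(cal_1k(), -5), "positive")
})

test_that("apparent MWCO inverts the sieving law at the 90% level", {
  mwco <- apparent_mwco(cal_1k(), 0.9)
  expect_lt(abs(mwco / 1445 - 1), 0.01)
  # closed form for the 3 kg/mol line
  expect_equal(apparent_mwco(cal_3k(), 0.9), 10^((0.9 + 2.666) / 1.0552),
               tolerance = 1e-12)
  # inverse identity inside the unclipped region
  for (lev in c(0.3, 0.6, 0.9)) {
    m <- apparent_mwco(cal_1k(), lev)
    expect_equal(retention_at(cal_1k(), m), lev, tolerance = 1e-9)
  }
  expect_error(apparent_mwco(cal_1k(), 1), "strictly between")
  expect_error(apparent_mwco(membrane_calibration(0, 0)), "positive slope")
  expect_error(membrane_calibration(-0.5, 0), "non-negative")
})
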