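test_that("single-line spectrum peaks at hc/E and conserves oscillator strength", {
  rec <- data.frame(energy_eV = 2.7605, osc_strength = 0.1)
  sp <- assemble_spectrum(rec)
  expect_equal(sp$n_records, 1L)
  bm <- band_metrics(to_wavelength(sp))
  expect_equal(bm$lambda_max_nm, 1239.842 / 2.7605, tolerance = 0.1 / 449)
  expect_equal(spectrum_integral(sp), 0.1, tolerance = 1e-6)
})

test_that("two close lines merge into a single symmetric maximum", {
  rec <- data.frame(energy_eV = c(2.70 - 0.01, 2.70 + 0.01),
                    osc_strength = c(0.05, 0.05))
  sp <- assemble_spectrum(rec, fwhm = 0.15)
  i <- which.max(sp$intensity)
  expect_equal(sp$energy_eV[i], 2.70, tolerance = 0.002)
})

test_that("assembly is linear: pooled ensembles equal the count-weighted mean", {
  set.seed(21)
  a <- data.frame(energy_eV = runif(40, 2.3, 2.9), osc_strength = runif(40))
  b <- data.frame(energy_eV = runif(60, 2.4, 3.2), osc_strength = runif(60))
  sab <- assemble_spectrum(rbind(a, b))
  sa <- assemble_spectrum(a); sb <- assemble_spectrum(b)
  mixed <- (40 * sa$intensity + 60 * sb$intensity) / 100
  expect_equal(sab$intensity, mixed, tolerance = 1e-12)
})

test_that("input validation rejects empty records and warns on truncated lines", {
  expect_error(assemble_spectrum(data.frame()), "non-empty")
  expect_error(assemble_spectrum(data.frame(energy_eV = -1, osc_strength = 1)),
               "> 0")
  expect_warning(
    assemble_spectrum(data.frame(energy_eV = 5.2, osc_strength = 0.1)),
    "outside the grid")
})

test_that("wavelength conversion applies hc = 1239.842 and an optional Jacobian", {
  rec <- data.frame(energy_eV = 2.0, osc_strength = 0.1)
  sp <- assemble_spectrum(rec)
  tr <- to_wavelength(sp)
  expect_equal(max(tr$wavelength_nm), 1239.842 / 1.5)
  expect_equal(min(tr$wavelength_nm), 1239.842 / 4.5)
  # no-jacobian conversion is a pure re-axis: intensities are preserved
  expect_equal(sort(tr$intensity), sort(sp$intensity))
  # the E^2 Jacobian weights the high-energy side: blue-shifted maximum
  broad <- assemble_spectrum(data.frame(energy_eV = 2.7, osc_strength = 1),
                             fwhm = 0.5)
  lm_plain <- band_metrics(to_wavelength(broad, jacobian = FALSE),
                           window = c(300, 800))$lambda_max_nm
  lm_jac <- band_metrics(to_wavelength(broad, jacobian = TRUE),
                         window = c(300, 800))$lambda_max_nm
  expect_lt(lm_jac, lm_plain)
})

test_that("band metrics find the maximum and the tail extent of a Gaussian band", {
  wl <- seq(380, 780, by = 0.25)
  y <- exp(-(wl - 455)^2 / (2 * 30^2))
  bm <- band_metrics(data.frame(wavelength_nm = wl, intensity = y))
  expect_equal(bm$lambda_max_nm, 455, tolerance = 1e-3)
  # closed form: crossing of 1% of peak at center + sigma*sqrt(2 ln 100)
  expect_equal(bm$tail_extent_nm, 455 + 30 * sqrt(2 * log(100)),
               tolerance = 0.25)
  bm1 <- band_metrics(data.frame(wavelength_nm = wl, intensity = y),
                      threshold_fraction = 1)
  expect_equal(bm1$tail_extent_nm, bm1$lambda_max_nm)
  expect_error(band_metrics(data.frame(wavelength_nm = wl,
                                       intensity = rep(1, length(wl)))),
               "flat")
})

test_that("cis-trans split preserves sign and vanishes for identical bands", {
  m_t <- list(lambda_max_nm = 481); m_c <- list(lambda_max_nm = 439)
  expect_equal(cis_trans_split(m_c, m_t), 42)
  expect_equal(cis_trans_split(m_t, m_t), 0)
  # planted n-orbital destabilisation of trans -> red-shifted trans band
  tr_ens <- gen_ensemble(profile_preset("dfdc_like", "trans"), n = 1500,
                         seed = 31, build_frames = FALSE)
  ci_ens <- gen_ensemble(profile_preset("dfdc_like", "cis"), n = 1500,
                         seed = 32, build_frames = FALSE)
  bm_tr <- band_metrics(to_wavelength(assemble_spectrum(tr_ens$records)))
  bm_ci <- band_metrics(to_wavelength(assemble_spectrum(ci_ens$records)))
  expect_gt(cis_trans_split(bm_ci, bm_tr), 0)
})

test_that("molar absorptivity follows Beer-Lambert with unit options", {
  sp <- experimental_spectrum(c(400, 450, 500), c(0.5, 0.25, 0),
                              concentration_M = 5e-4, path_cm = 1)
  eps <- epsilon_from_absorbance(sp)
  expect_equal(eps$epsilon, c(1000, 500, 0))
  eps2 <- epsilon_from_absorbance(sp, unit = "L_mmol_cm")
  expect_equal(eps2$epsilon, c(1, 0.5, 0))
  # round trip back to absorbance
  expect_equal(eps$epsilon * 5e-4 * 1, sp$absorbance)
  no_meta <- experimental_spectrum(c(400, 450), c(0.1, 0.2))
  expect_error(epsilon_from_absorbance(no_meta), "metadata")
})

test_that("spectrum integral equals mean oscillator strength for interior lines", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(50:300, 1)
    rec <- data.frame(energy_eV = runif(n, 2.3, 3.7),
                      osc_strength = runif(n, 0, 0.3))
    sp <- assemble_spectrum(rec)
    expect_equal(spectrum_integral(sp), mean(rec$osc_strength),
                 tolerance = 1e-6)
  }
})

test_that("shift calibration recovers zero and planted shifts", {
  set.seed(55)
  rec <- data.frame(energy_eV = rnorm(400, 2.7, 0.1),
                    osc_strength = runif(400, 0.02, 0.1))
  sp <- assemble_spectrum(rec)
  ident <- gen_experimental_spectrum(sp, shift_eV = 0, scale = 1, seed = 1)
  cal0 <- calibrate_shift(sp, ident)
  expect_equal(cal0$shift_eV, 0, tolerance = 2e-3)
  expect_equal(cal0$scale, 1, tolerance = 1e-3)

  planted <- gen_experimental_spectrum(sp, shift_eV = 0.15, scale = 2.5, seed = 2)
  cal <- calibrate_shift(sp, planted)
  expect_equal(cal$shift_eV, 0.15, tolerance = 2e-3)
  expect_equal(cal$scale, 2.5, tolerance = 0.01)
  expect_equal(cal$shifted$shift_eV, cal$shift_eV)

  noisy <- gen_experimental_spectrum(sp, shift_eV = -0.12, scale = 2,
                                     noise_frac = 0.05, seed = 3)
  caln <- calibrate_shift(sp, noisy)
  expect_equal(caln$shift_eV, -0.12, tolerance = 0.01)

  expect_error(calibrate_shift(sp, ident, window = c(900, 1000)),
               "overlap")
})
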