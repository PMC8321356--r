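test_that("polychromatic absorption rate matches direct two-term evaluation", {
  sp <- two_line_spectrum()
  cv <- toy_curve(0.2, 0.1)
  # oracle: -log(0.5 exp(-2) + 0.5 exp(-1))
  expect_equal(absorption_rate(sp, cv, thickness = 10),
               hand_absorption(c(1, 1), c(0.2, 0.1), 10), tolerance = 1e-12)
  # zero thickness absorbs nothing
  expect_equal(absorption_rate(sp, cv, thickness = 0), 0)
  # monochromatic case reduces to kappa * L exactly
  mono <- delta_spectrum(30)
  expect_equal(absorption_rate(mono, cv, thickness = 1), 0.2,
               tolerance = 1e-14)
  expect_equal(absorption_rate(mono, cv, thickness = 7.3), 0.2 * 7.3,
               tolerance = 1e-12)
})

test_that("multi-layer stacks sum attenuation along the ray", {
  sp <- two_line_spectrum()
  stack <- material_stack(list(toy_curve(0.2, 0.1), toy_curve(0.4, 0.3)),
                          c(2, 1))
  expect_equal(absorption_rate(sp, stack),
               hand_absorption(c(1, 1), c(0.2 * 2 + 0.4, 0.1 * 2 + 0.3), 1),
               tolerance = 1e-12)
})

test_that("effective attenuation is the intensity-weighted mean of the curve", {
  expect_equal(effective_attenuation(two_line_spectrum(), toy_curve()), 0.15)
  expect_equal(effective_attenuation(delta_spectrum(30), toy_curve()), 0.2)
  # thin-object limit: absorption_rate(L)/L -> keff
  sp <- two_line_spectrum(c(2, 1))
  keff <- effective_attenuation(sp, toy_curve())
  L <- 1e-4
  expect_equal(absorption_rate(sp, toy_curve(), thickness = L) / L, keff,
               tolerance = 1e-4)
})

test_that("dual-energy ratio is constant for monochromatic pairs and drifts otherwise", {
  cv <- toy_curve(0.2, 0.1)
  r <- ratio_curve(delta_spectrum(30), delta_spectrum(60), cv, c(0.5, 3, 10))
  expect_equal(r, rep(2, 3), tolerance = 1e-12)

  # polychromatic spec1 (kappas 0.2, 0.1) vs monochromatic spec2 at
  # kappa = 0.05: thickness dependence appears
  sp1 <- two_line_spectrum()
  cv2 <- attenuation_curve(c(30, 60, 100), c(0.2, 0.1, 0.05), "toy3")
  sp2 <- delta_spectrum(100, voltage = 100)
  # L -> 0: keff1 / kappa2 = 0.15 / 0.05 = 3
  expect_equal(ratio_curve(sp1, sp2, cv2, 1e-5), 3, tolerance = 1e-3)
  # L = 10: hand evaluation of numerator, exact monochromatic denominator
  expect_equal(ratio_curve(sp1, sp2, cv2, 10),
               hand_absorption(c(1, 1), c(0.2, 0.1), 10) /
                 (0.05 * 10), tolerance = 1e-12)

  expect_error(ratio_curve(sp1, sp2, cv2, c(1, 0)), "undefined")
})

test_that("muscle ratio under the shipped 40/90 kV spectra decreases with thickness", {
  lo <- make_spectrum(40)
  hi <- make_spectrum(90)
  r <- ratio_curve(lo, hi, muscle_attenuation(),
                   seq(0.01, 20, length.out = 200))
  expect_true(all(diff(r) < 0))
})

test_that("ratio of a spectrum with itself is identically one", {
  sp <- make_spectrum(90)
  r <- ratio_curve(sp, sp, muscle_attenuation(), c(0.1, 1, 5, 15))
  expect_equal(r, rep(1, 4), tolerance = 1e-12)
})

test_that("beam hardening: polychromatic absorption is increasing and concave in thickness", {
  sp <- make_spectrum(90)
  cv <- muscle_attenuation()
  L <- seq(0.5, 20, by = 0.5)
  m <- vapply(L, function(l) absorption_rate(sp, cv, thickness = l),
              numeric(1))
  expect_true(all(diff(m) > 0))
  expect_true(all(diff(diff(m)) < 0))
  # monochromatic: exactly linear
  mono <- delta_spectrum(60)
  mm <- vapply(L, function(l) absorption_rate(mono, cv, thickness = l),
               numeric(1))
  expect_equal(mm, mu_at(cv, 60) * L, tolerance = 1e-12)
})

test_that("parametric tube spectrum behaves like filtered bremsstrahlung", {
  sp <- make_spectrum(90)
  expect_true(max(sp$energies) <= 90)
  raw <- make_spectrum(90, filtration_mm_al = 0)
  i10 <- raw$intensities[raw$energies == 10]
  i80 <- raw$intensities[raw$energies == 80]
  expect_gt(i10, i80)
  # filtration hardens the beam
  expect_gt(mean_energy(make_spectrum(90, filtration_mm_al = 2)),
            mean_energy(raw))
  expect_error(make_spectrum(10), "out of range")
  expect_error(make_spectrum(200), "out of range")
})

test_that("invalid spectra and out-of-range energies are rejected", {
  expect_error(spectrum(c(30, 60), c(0, 0), 90), "all intensities are zero")
  expect_error(spectrum(c(30, 60), c(1, -1), 90), "nonnegative")
  expect_error(spectrum(c(60, 30), c(1, 1), 90), "strictly increasing")
  expect_error(spectrum(c(30, 95), c(1, 1), 90), "voltage")
  # spectrum support outside the curve range
  sp <- spectrum(c(15, 80), c(1, 1), 90)
  expect_error(absorption_rate(sp, toy_curve(), thickness = 1),
               "range error")
})

test_that("attenuation CSV round trip and shipped curves are monotone", {
  for (cv in list(muscle_attenuation(), bone_attenuation(),
                  aluminum_attenuation())) {
    expect_true(all(diff(cv$mu) < 0))
    expect_true(all(cv$mu > 0))
  }
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(energy_keV = c(20, 40, 80),
                       mu_per_cm = c(0.9, 0.4, 0.25)), tmp, row.names = FALSE)
  cv <- read_attenuation_csv(tmp, "tmp")
  expect_equal(mu_at(cv, 40), 0.4, tolerance = 1e-12)
  # log-log interpolation stays within the bracketing values
  expect_true(mu_at(cv, 30) < 0.9 && mu_at(cv, 30) > 0.4)
})
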