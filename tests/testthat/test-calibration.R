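# Calibration fitting, LOD bookkeeping, and concentration quantification.

test_that("a noiseless proportional table gives the exact slope and zero LOD", {
  tab <- tibble::tibble(
    concentration_ug_per_ml = c(0, 0, 5, 10, 50, 100),
    amplitude = 2.5 * c(0, 0, 5, 10, 50, 100)
  )
  cal <- fit_calibration(tab)
  expect_equal(cal$slope, 2.5, tolerance = 1e-12)
  expect_equal(cal$lod, 0, tolerance = 1e-12)
  expect_equal(glance(cal)$n_blanks, 2)
  expect_equal(tidy(cal)$estimate, 2.5, tolerance = 1e-12)
})

test_that("degenerate tables are rejected with the deficiency named", {
  blanks_only <- tibble::tibble(
    concentration_ug_per_ml = rep(0, 6), amplitude = rnorm(6)
  )
  expect_error(fit_calibration(blanks_only), "non-zero concentrations")
  two_levels <- tibble::tibble(
    concentration_ug_per_ml = c(0, 5, 5, 10), amplitude = c(0, 5, 5.1, 10)
  )
  expect_error(fit_calibration(two_levels), "non-zero concentrations")
})

test_that("quantification is amplitude over slope, with below-LOD flagging", {
  tab <- tibble::tibble(
    concentration_ug_per_ml = c(0, 0, 0, 10, 50, 100),
    amplitude = c(0.2, -0.1, 0.15, 10, 50, 100) * 2.546
  )
  cal <- fit_calibration(tab)
  dem <- tibble::tibble(
    wavelength = c(680, 685, 690),
    amplitude = c(100, 254.6, 300), noise_floor = 1
  )
  class(dem) <- c("demodulated_spectrum", class(dem))
  q <- quantify(dem, cal, ref_wavelength = 685)
  expect_equal(q$concentration_ug_per_ml, 254.6 / cal$slope, tolerance = 1e-9)
  expect_false(q$below_detection)

  dem$amplitude[2] <- 0
  q0 <- quantify(dem, cal, ref_wavelength = 685)
  expect_equal(q0$concentration_ug_per_ml, 0)
  expect_true(q0$below_detection)
  expect_error(quantify(dem, cal, ref_wavelength = 999), "wavelength grid")
})

test_that("closed-loop quantification at 100 ug/mL is accurate to a few percent", {
  cfg <- modulation_config()
  model <- spectrum_model()
  cal <- fit_calibration(simulate_calibration_series(
    model, cfg, c(0, 0, 0, 10, 50, 100, 200),
    seed = 99, noise = "none"
  ))
  rel_err <- vapply(1:40, function(s) {
    sp <- simulate_modulated_spectrum(model, cfg, 100, seed = s)
    q <- quantify(demodulate(sp), cal)
    abs(q$concentration_ug_per_ml - 100) / 100
  }, numeric(1))
  expect_lt(mean(rel_err), 0.05)
})

test_that("end-to-end response is linear with unit slope after calibration (noiseless)", {
  cfg <- modulation_config()
  model <- spectrum_model(drift_fraction = 0)
  cal <- fit_calibration(simulate_calibration_series(
    model, cfg, c(0, 10, 50, 100),
    seed = 1, noise = "none"
  ))
  concs <- c(5, 20, 80, 160)
  est <- vapply(concs, function(conc) {
    sp <- simulate_modulated_spectrum(model, cfg, conc, noise = "none")
    quantify(demodulate(sp), cal)$concentration_ug_per_ml
  }, numeric(1))
  expect_equal(est, concs, tolerance = 1e-8)
})

test_that("recovered concentrations are unbiased with honest interval coverage", {
  # 100 seeded replicates at default noise: bias < 2% and ~95% of +/-2 SE
  # intervals (SE from the replicate spread) cover the truth
  cfg <- modulation_config()
  model <- spectrum_model()
  cal <- fit_calibration(simulate_calibration_series(
    model, cfg, c(0, 0, 0, 10, 50, 100, 200),
    seed = 7, noise = "none"
  ))
  est <- vapply(1:100, function(s) {
    sp <- simulate_modulated_spectrum(model, cfg, 50, seed = 1000 + s)
    quantify(demodulate(sp), cal)$concentration_ug_per_ml
  }, numeric(1))
  expect_lt(abs(mean(est) - 50) / 50, 0.02)
  covered <- abs(est - 50) <= 2 * sd(est)
  expect_gte(mean(covered), 0.90)
})
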