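# Forward simulator for modulated spectra: analytic anchors, noise realism,
# determinism, and contract errors.

test_that("square-wave fundamental matches 2 m I0 / pi in the fine-sampling limit", {
  # 8000 samples per period: discrete-sampling correction ~2.6e-8, below the
  # 1e-6 tolerance of the analytic anchor
  cfg <- modulation_config(depth_m = 0.2, sample_rate = 16000, duration = 1)
  model <- flat_model() # 500 counts/s per ug/mL at 685, no background
  sp <- simulate_modulated_spectrum(model, cfg, fnd_conc = 2, noise = "none")
  dem <- demodulate(sp)
  i <- which(dem$wavelength == 685)
  expected <- 2 * 0.2 * 1000 / pi # I0 = 2 ug/mL * 500 = 1000 counts/s
  expect_lt(abs(dem$amplitude[i] - expected) / expected, 1e-6)
})

test_that("noiseless demodulation reproduces the recorded discrete truth exactly", {
  cfg <- modulation_config(depth_m = 0.15)
  model <- spectrum_model(background_level = 2000)
  sp <- simulate_modulated_spectrum(model, cfg, 40, noise = "none")
  dem <- demodulate(sp)
  expect_equal(dem$amplitude, sp$truth$amplitude_discrete, tolerance = 1e-10)
})

test_that("zero modulation depth leaves nothing above the Poisson noise floor", {
  cfg <- modulation_config(depth_m = 0)
  sp <- simulate_modulated_spectrum(spectrum_model(), cfg, 100, seed = 11)
  dem <- demodulate(sp)
  # amplitude at f_mod is one more Rayleigh draw; the largest ratio to the
  # off-frequency median across 251 wavelengths stays far below 6
  expect_lt(max(dem$amplitude / dem$noise_floor), 6)
})

test_that("demodulated amplitude is linear in concentration (noiseless)", {
  cfg <- modulation_config()
  model <- spectrum_model(background_level = 1000)
  a1 <- demodulate(simulate_modulated_spectrum(model, cfg, 25, noise = "none"))
  a2 <- demodulate(simulate_modulated_spectrum(model, cfg, 50, noise = "none"))
  expect_equal(a2$amplitude, 2 * a1$amplitude, tolerance = 1e-10)
})

test_that("shot noise is Poisson: variance/mean near 1 at 1e5 samples", {
  # constant rate (no modulation, no drift, no background structure)
  cfg <- modulation_config(depth_m = 0, sample_rate = 20, duration = 5000)
  model <- flat_model(background_level = 0)
  sp <- simulate_modulated_spectrum(model, cfg, 10, seed = 21)
  x <- sp$intensities[2, ] # 250 expected counts/sample at 685
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
})

test_that("identical seeds give identical spectra; seeds differ otherwise", {
  cfg <- modulation_config()
  m <- spectrum_model()
  a <- simulate_modulated_spectrum(m, cfg, 50, seed = 5)
  b <- simulate_modulated_spectrum(m, cfg, 50, seed = 5)
  c <- simulate_modulated_spectrum(m, cfg, 50, seed = 6)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("invalid inputs are rejected with the violated invariant named", {
  expect_error(
    simulate_modulated_spectrum(spectrum_model(), modulation_config(), -1),
    "fnd_conc"
  )
  expect_error(modulation_config(duration = 60.3), "integer number of periods")
  expect_error(modulation_config(depth_m = 1), "depth_m")
  expect_error(modulation_config(sample_rate = 5), "sample_rate")
})

test_that("calibration series over the labeling range is monotone with near-zero blanks", {
  cfg <- modulation_config(duration = 30)
  tab <- simulate_calibration_series(
    spectrum_model(), cfg,
    concentrations = c(0, 5, 10, 50, 100, 200), replicates = 3, seed = 31
  )
  means <- tapply(tab$amplitude, tab$concentration_ug_per_ml, mean)
  expect_true(all(diff(means) > 0))
  # blank amplitudes sit at the noise floor, far below the smallest standard
  expect_lt(means[["0"]], means[["5"]] / 3)
})

test_that("noiseless calibration series is exactly proportional to concentration", {
  tab <- simulate_calibration_series(
    flat_model(), modulation_config(), c(0, 5, 10, 50),
    seed = 1, noise = "none"
  )
  nz <- tab$concentration_ug_per_ml > 0
  slopes <- tab$amplitude[nz] / tab$concentration_ug_per_ml[nz]
  expect_lt(diff(range(slopes)) / mean(slopes), 1e-10)
  expect_equal(tab$amplitude[!nz], 0, tolerance = 1e-12)
})
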