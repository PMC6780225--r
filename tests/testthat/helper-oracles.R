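# Independent oracles and small builders shared by the tests.

# Brute-force lock-in: project the time series onto sin/cos at f_mod by
# direct summation and return the one-sided amplitude in counts/s. Kept
# deliberately free of fft() so it can cross-check the FFT path.
lockin_amplitude <- function(x, f_mod, sample_rate) {
  n <- length(x)
  t <- (seq_len(n) - 1) / sample_rate
  re <- sum(x * cos(2 * pi * f_mod * t))
  im <- sum(x * sin(2 * pi * f_mod * t))
  2 * sqrt(re^2 + im^2) / n * sample_rate
}

# Minimal flat-spectrum model: FND and background rates equal at every
# wavelength, so per-channel rates are read straight off the parameters.
flat_model <- function(wavelengths = c(684, 685, 686),
                       brightness_per_conc = 500, background_level = 0,
                       drift_fraction = 0) {
  spectrum_model(
    wavelengths = wavelengths,
    brightness_per_conc = brightness_per_conc,
    background_level = background_level,
    drift_fraction = drift_fraction
  )
}

# Exactly binned single-exponential decay histogram (no sampling noise).
exact_exp_histogram <- function(tau, bin_width = 0.2, n_bins = 320,
                                total = 1e6) {
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  p <- exp(-edges[-length(edges)] / tau) - exp(-edges[-1] / tau)
  decay_histogram(edges, total * p)
}

expect_within <- function(value, center, halfwidth) {
  expect_true(
    abs(value - center) <= halfwidth,
    label = sprintf("%g within %g of %g", value, halfwidth, center)
  )
}
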