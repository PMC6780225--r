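# Decay simulation, time gating, lifetime estimation, gated imaging.

test_that("pure FND decay has mean arrival time tau within sampling error", {
  # long range (200 ns ~ 12 tau) so truncation is negligible
  m <- decay_model(fraction_fnd = 1, irf_sigma = 0, n_bins = 1000, total_photons = 1e5)
  h <- simulate_decay_histogram(m, seed = 51)
  centers <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  emp_mean <- sum(centers * h$counts) / sum(h$counts)
  expect_within(emp_mean, 17, 4 * 17 / sqrt(1e5))
})

test_that("autofluorescence tail probability matches the exponential law", {
  m <- decay_model(
    tau_auto = 2, fraction_fnd = 0, irf_sigma = 0,
    n_bins = 500, total_photons = 1e5
  )
  h <- simulate_decay_histogram(m, seed = 52)
  frac <- gate(h, 10)$retained_fraction
  p <- exp(-10 / 2)
  expect_within(frac, p, 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("zero photons give an all-zero histogram without failure", {
  h <- simulate_decay_histogram(decay_model(total_photons = 0), seed = 1)
  expect_true(all(h$counts == 0))
  expect_error(estimate_lifetime(h), "tail")
})

test_that("a too-short histogram range warns about truncation bias", {
  expect_warning(
    simulate_decay_histogram(
      decay_model(n_bins = 100, bin_width = 0.2, total_photons = 100),
      seed = 1
    ),
    "truncation"
  )
})

test_that("gating conserves photons and is monotone in the gate delay", {
  h <- simulate_decay_histogram(decay_model(), seed = 53)
  total <- sum(h$counts)
  gates <- seq(0, 40, by = 2.5)
  res <- vapply(gates, function(g) gate(h, g)$retained_fraction, numeric(1))
  expect_equal(gate(h, 0)$retained_fraction, 1)
  expect_equal(gate(h, 0)$retained_counts, total)
  expect_true(all(diff(res) <= 1e-12))
  # retained + rejected = total at a partial-bin gate
  g <- gate(h, 10.07)
  expect_lte(g$retained_counts, total)
  expect_equal(g$retained_counts + (total - g$retained_counts), total)
  expect_error(gate(h, 100), "last bin edge")
})

test_that("retention matches exp(-t_gate/tau) across lifetimes and gates", {
  for (tau in c(2, 5, 17)) {
    m <- decay_model(
      tau_fnd = tau + 1e-9, tau_auto = tau, fraction_fnd = 0, irf_sigma = 0,
      bin_width = 0.2, n_bins = ceiling(15 * tau / 0.2), total_photons = 5e4
    )
    h <- simulate_decay_histogram(m, seed = round(100 * tau))
    for (tg in c(2, 5, 10)) {
      p <- exp(-tg / tau)
      expect_within(
        gate(h, tg)$retained_fraction, p,
        3 * sqrt(p * (1 - p) / 5e4)
      )
    }
  }
})

test_that("gating always favors the long-lived FND component", {
  for (seed in 1:5) {
    h <- simulate_decay_histogram(decay_model(), seed = seed)
    g <- gate(h, 10)
    expect_gt(g$snr_gain, 1)
    expect_gt(g$fnd_retention, g$auto_retention)
  }
})

test_that("lifetime fit is exact on a noiseless single exponential", {
  h <- exact_exp_histogram(tau = 17)
  fit <- estimate_lifetime(h, fit_start = 8)
  expect_lt(abs(fit$tau - 17) / 17, 0.01)
  expect_equal(tidy(fit)$estimate, fit$tau)
})

test_that("simulated FND histograms support the tau > 15 ns claim in >= 95% of seeds", {
  m <- decay_model(fraction_fnd = 1, total_photons = 1e5)
  taus <- vapply(1:100, function(s) {
    estimate_lifetime(simulate_decay_histogram(m, seed = s), fit_start = 8)$tau
  }, numeric(1))
  expect_gte(mean(taus > 15), 0.95)
})

test_that("gated images keep puncta contrast and reject background", {
  f <- matrix(0, 24, 24)
  f[c(6, 12, 18), c(6, 12, 18)] <- 0.9 # 9 FND puncta over autofluorescence
  m <- decay_model(n_bins = 320)
  st <- simulate_decay_stack(f, m, photons_per_pixel = 800, seed = 61)

  g0 <- gated_image(st, 0)
  expect_equal(g0$gated, g0$ungated)

  g <- gated_image(st, 10)
  mask <- f > 0
  contrast_gated <- mean(g$gated[mask]) / mean(g$gated[!mask])
  contrast_ungated <- mean(g$ungated[mask]) / mean(g$ungated[!mask])
  expect_gt(contrast_gated, contrast_ungated)

  # background-only stack decays like the autofluorescence tail
  bg <- simulate_decay_stack(
    matrix(0, 16, 16), decay_model(irf_sigma = 0),
    photons_per_pixel = 1000, seed = 62
  )
  gb <- gated_image(bg, 10)
  ratio <- mean(gb$gated) / mean(gb$ungated)
  expect_within(ratio, exp(-10 / 2.5), 0.005)

  st$bin_edges <- st$bin_edges[-1]
  expect_error(gated_image(st, 5), "bin")
})
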