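# fndtrace

Quantification and long-term tracking of cells labeled with fluorescent
nanodiamonds (FNDs), for groups using FND-labeled stem cells in
regenerative-medicine studies and anyone building assays on NV⁻-center
photophysics.

FNDs host NV⁻ color centers: photostable far-red emitters (600–800 nm)
whose fluorescence drops by a fraction *m* under a magnetic field and whose
lifetime (τ > 15 ns) far exceeds tissue autofluorescence (τ ≈ 1–4 ns).
`fndtrace` implements the computations these two handles enable:

* **Magnetically modulated fluorescence (MMF).** A square-wave field
  (2 Hz, 20 mT) toggles the FND count rate between I₀ and I₀(1−m);
  `demodulate()` extracts, per wavelength, the one-sided DFT amplitude
  2|X(k_mod)|/N at the modulation bin. For a 50%-duty square wave this
  amplitude is 2mI₀/π, and only the FND component carries it — constant or
  slowly drifting autofluorescence contributes nothing. A through-origin
  calibration (`fit_calibration()`, LOD = 3.3·σ_blank/slope) turns
  amplitudes into concentrations (`quantify()`), and `mass_to_particles()` /
  `per_cell_loading()` convert recovered mass into particle counts per cell.
* **Time gating.** `gate()`, `estimate_lifetime()` and `gated_image()`
  reject short-lifetime background from photon arrival-time histograms and
  per-pixel decay stacks: a 10 ns gate keeps e^(−10/17) ≈ 56% of FND
  photons but only e^(−10/2.5) ≈ 2% of autofluorescence.
* **Field quantification.** `count_nuclei()` (smooth → Otsu → connected
  components → area filter), `detect_fnd_cells()` (perinuclear-annulus
  test), Manders colocalization with a block-scramble control, and
  mean ± SEM summaries over random fields per section.
* **Forward simulators** for every input — modulated spectra, calibration
  series, decay histograms and stacks, multichannel histology fields — with
  ground truth recorded, so the whole pipeline is testable end to end
  (`simulate_*()`, `run_pipeline()`, `make_fixtures()`).

Everything is tibble-in/tibble-out with `tidy()`/`glance()`/`autoplot()`
methods on fitted objects.

## Worked example

Calibrate, then quantify a simulated tissue digest spiked at 50 µg/mL whose
autofluorescence is ten times the FND count rate:

```r
library(fndtrace)

cfg   <- modulation_config()                  # 2 Hz, 20 mT, m = 0.10, 60 s @ 20 Hz
model <- spectrum_model()                     # 500 counts/s per (ug/mL) at 685 nm
cal <- fit_calibration(simulate_calibration_series(
  model, cfg, c(0, 0, 0, 5, 10, 50, 100, 200), seed = 42))
glance(cal)
#>   slope intercept residual_sd blank_sd   lod     n n_blanks
#> 1  32.3         0        24.8     8.37 0.856     8        3

digest <- spectrum_model(background_level = 10 * 50 * 500)
sp <- simulate_modulated_spectrum(digest, cfg, fnd_conc = 50, seed = 42)
quantify(demodulate(sp), cal)
#>   concentration_ug_per_ml amplitude noise_floor   lod below_detection
#> 1                    49.6     1599.        110. 0.856 FALSE
```

The calibration slope is 32.3 counts/s per µg/mL (analytically
2mB/π · sampling correction ≈ 32.4 at m = 0.10, B = 500), the detection
limit 0.86 µg/mL, and the spiked 50 µg/mL comes back as 49.6 — a 99%
recovery despite a 10× background. Mass bookkeeping at the observed
per-cell loading:

```r
mass_to_particles(49.3)
#>   mass_pg particles particles_2sf
#> 1    49.3    26749.         27000
```

49.3 pg/cell of 100 nm FNDs is ~2.7 × 10⁴ particles per cell. Time gating
on a half-FND, half-background histogram:

```r
gate(simulate_decay_histogram(decay_model(), seed = 42), t_gate = 10)
#>   t_gate total_counts retained_counts retained_fraction fnd_retention auto_retention snr_gain
#> 1     10        94770          27632.             0.292         0.553         0.0214     25.8
```

The gate keeps 55% of FND photons versus 2.1% of background — a 26×
signal-to-background gain — and the tail fit on a pure-FND histogram
returns τ = 16.9 ± 0.1 ns, supporting the τ > 15 ns identification. A
simulated histology field closes the loop:

```r
quantify_field(simulate_field(field_spec(marker_positive_fraction = 0.8), seed = 42))
#>   field_id n_nuclei n_fnd_positive coloc_m1 coloc_m2
#> 1        1       25             25    0.716    0.917
```

All 25 ground-truth nuclei are found and all are FND-positive (the
simulated labeled fraction is 1); 72% of above-threshold FND intensity
lies on the marker.

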