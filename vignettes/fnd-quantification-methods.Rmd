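---
title: "Methods: background-free FND quantification, time gating, and field counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: background-free FND quantification, time gating, and field counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(fndtrace)
```

Fluorescent nanodiamonds (FNDs) host NV⁻ color centers: photostable far-red
emitters (600–800 nm, zero-phonon line near 638 nm, phonon sideband near
685 nm) whose fluorescence is partially quenched by a magnetic field and
whose lifetime (τ > 15 ns) far exceeds that of tissue autofluorescence
(τ ≈ 1–4 ns). These two physical handles make FND-labeled cells quantifiable
and imageable against strong biological background. `fndtrace` implements
the corresponding computations — magnetically modulated fluorescence (MMF)
demodulation with calibration-based quantification, lifetime-based time
gating, and field-based cell counting — together with forward simulators
that carry the ground truth each stage is tested against.

## The MMF forward model and demodulation

During an MMF acquisition a square-wave magnetic field (2 Hz, 20 mT, 50%
duty, field-off first) toggles the FND count rate between $I_0$ and
$I_0(1-m)$, where $m$ is the modulation depth; autofluorescence does not
respond to the field. At each wavelength the detected counts are Poisson
around

$$\lambda(\lambda_i, t) = c\,B\,s(\lambda_i)\,[1 - m\,\mathrm{sq}(t)] +
  A\,a(\lambda_i)\,[1 + d\sin(2\pi t/T_d)],$$

with $c$ the FND concentration (µg/mL), $B$ the brightness at the 685 nm
reference channel (counts·s⁻¹ per µg/mL), $s$ and $a$ the FND and
autofluorescence spectral shapes, $A$ the background level and $d$ the slow
drift amplitude. Demodulation takes, per wavelength, the one-sided DFT
amplitude at the modulation bin, $2|X(k_{\mathrm{mod}})|/N$ (scaled to
counts/s). For a 50%-duty square wave the fundamental amplitude is
$2 m I_0/\pi$, which anchors the convention analytically.

Numerical choices:

* **Integer periods by construction.** `modulation_config()` requires
  `duration * f_mod` to be a whole number, so the modulation frequency falls
  exactly on a DFT bin and there is no spectral leakage of the signal. If a
  recorded trace violates this, `demodulate(window = "hann")` applies a Hann
  window fallback and flags the result.
* **Finite-sampling correction.** A square wave sampled at $N_p$ points per
  period carries $(\pi/N_p)/\sin(\pi/N_p)$ times more amplitude in its
  fundamental bin than the continuous-time value (about +1.7% at the default
  10 samples/period). Simulators record both the continuous-convention truth
  and the exact discrete amplitude; quantification is immune because the
  calibration slope carries the same factor and it cancels.
* **Noise floor.** The off-frequency amplitude floor is the median over bins
  at least 3 bins away from the modulation bin and its odd harmonics — a
  square wave necessarily puts power at $3f, 5f, \dots$, and the median is
  robust to them.
* **Fundamental only.** Harmonics are not summed into the signal estimate;
  the single-frequency convention keeps the analytic anchor exact and costs
  only a constant factor that calibration absorbs.
* **Drift rejection.** Multiplicative background drift (default: sinusoid
  with 60 s period, 5% amplitude, applied to autofluorescence only) is the
  disturbance MMF exists to remove. Backgrounds varying slower than
  $f_{\mathrm{mod}}/10$ perturb the demodulated amplitude by well under 1%
  of the true amplitude — verified as a property, not assumed.

### Calibration and detection limit

The calibration regression is least squares **through the origin**: MMF is
background-free by construction, so a free intercept only inflates
variance; blank acquisitions inform the noise floor instead. The limit of
detection follows the ICH-style definition
$\mathrm{LOD} = 3.3\,\sigma_{\mathrm{blank}}/\mathrm{slope}$, with
$\sigma_{\mathrm{blank}}$ the SD of demodulated blank amplitudes (the
residual SD stands in when a table carries no blanks). Concentration
estimates below the LOD are returned but flagged, never censored.

Because blank amplitudes are magnitudes of a complex noise vector, they are
Rayleigh rather than Gaussian; at the default photon budget this inflates
the blank mean slightly but leaves the LOD bookkeeping conservative.

### Modulation depth

The fractional quench at 20 mT is treated phenomenologically: `depth_m`
defaults to 0.10, a typical NV⁻ quench magnitude at tens of mT, and is
exposed as a parameter everywhere. No spin-Hamiltonian model is attempted.
Likewise the sampling of the multichannel analyzer (20 samples/s, 60 s) is
a package default chosen to give 120 modulation periods per acquisition.

### Mass and particle bookkeeping

Recovered concentrations convert to particle counts through a spherical
particle of bulk diamond, $m_p = \rho\,\pi d^3/6$ with $d = 100$ nm and
$\rho = 3.52$ g/cm³ (a physical constant, not a fitted value):

```{r particles}
mass_to_particles(49.3)
per_cell_loading(4.93e6, 1e5)
```

49.3 pg per cell is about $2.7\times10^4$ particles — the scale of loading
observed when stem cells are labeled at 100 µg/mL for four hours.

## Time gating

Photon arrival histograms are two-component exponential mixtures (FND
τ = 17 ns, autofluorescence τ = 2.5 ns by default — values inside the
stated physical bounds τ > 15 ns and 1–4 ns) observed through a Gaussian
instrument response, simulated in continuous time and then binned. A gate
at $t_g$ retains photons arriving at or after $t_g$, splitting
boundary-straddling bins pro-rata. The default $t_g = 10$ ns rejects
$1-e^{-10/2.5} \approx 98\%$ of the background while keeping
$e^{-10/17} \approx 56\%$ of FND photons; no gate value is prescribed by
the physics, only the separation of lifetimes.

```{r gate}
h <- simulate_decay_histogram(decay_model(total_photons = 5e4), seed = 1)
gate(h, 10)
```

Lifetime estimation is a tail-only weighted log-linear fit (weights equal
to counts, variance of log of a Poisson count ≈ 1/count) from `fit_start`
(default 8 ns) onward. That supports the threshold claim τ > 15 ns without
instrument-response deconvolution or multi-exponential unmixing, which are
out of scope. `gated_image()` applies the same gate per pixel of a decay
stack and returns the gated and ungated images for contrast comparison.

## Field counting and colocalization

The counting operator is deliberately simple and fully reproducible:
Gaussian smoothing at half the expected nucleus radius, a global Otsu
threshold, connected components, and a minimum-area filter of
$\pi (r/2)^2$ pixels. Because thresholds are data-driven, counting is
invariant to global intensity scaling. The simulator places nuclei with a
hard-core rejection rule (no two centers closer than twice the sum of
their radii), so components never merge at default settings; a
distance-transform watershed is available behind a flag for real tissue
where nuclei touch.

A nucleus is FND-positive when the mean FND intensity in its perinuclear
annulus — between one and two equivalent radii from the centroid —
exceeds the FND channel's Otsu threshold. The annulus is circular rather
than a morphological dilation of the label; for the simulator's round
nuclei the two are equivalent, and the circular form is cheap and
deterministic.

Colocalization uses Manders split coefficients with per-channel Otsu
thresholds: $M_1$ is the fraction of above-threshold FND intensity lying
where the marker is also above threshold, $M_2$ the symmetric quantity.
The metric choice was open; Manders with data-driven thresholds was chosen
for robustness to intensity scaling, and `scramble_control()` (block
permutation of one channel) provides the chance-overlap baseline any
reported coefficient should be compared against. Coefficients are
undefined (NA, flagged) when a channel is constant.

```{r field}
fld <- simulate_field(field_spec(n_nuclei = 12, marker_positive_fraction = 0.8),
  seed = 2)
quantify_field(fld)
```

Per-section summaries stop at mean ± SEM over the (typically six) random
fields; group-comparison statistics are deliberately excluded from the
report — they belong to the analysis of a concrete experiment, not to the
pipeline.

## What the simulators do and do not emulate

The generators reproduce the statistical structure the analysis relies on:
Poisson shot noise on spectrally structured count rates, square-wave
modulation of only the FND component, slow multiplicative background
drift, biexponential decay mixtures with Gaussian IRF jitter, and fields
of well-separated Gaussian-profile nuclei with perinuclear FND puncta over
a diffuse endosomal haze. They do **not** emulate: detector afterpulsing
or dead time, spectral overlap between DAPI/FND/marker channels, spatially
varying illumination, chromatic aberration, nuclei that touch or overlap,
or section-to-section staining variability. Passing tests therefore
demonstrate correctness of the operators under the model's assumptions,
not segmentation robustness on difficult real tissue — the watershed flag
and data-driven thresholds are the extension points for that.

Default study conditions: labeling concentrations span 5–200 µg/mL;
spike-recovery simulations use autofluorescence at 10× the FND count rate
with 5% drift; calibration series use brightness 500 counts·s⁻¹ per µg/mL
and background 10⁴ counts/s at 685 nm. Rendering intensities in the field
simulator (nucleus peak 1, cytoplasmic haze 0.5, puncta 0.6, read noise
SD 0.05) were fixed once so that the three intensity populations —
background, haze, puncta — are distinct in the sense the Otsu operators
assume.

## Problem sizes and determinism

Simulation-backed checks use 60–120 s acquisitions at 20 samples/s
(1 200–2 400 samples across 251 wavelength channels), 10⁵-photon
histograms, and 256×256 px fields; closed-loop statistical claims use
50–100 seeded replicates. Every simulator takes an explicit seed and
touches no global RNG state; the pipeline derives per-stage seeds from one
master seed, so stages rerun standalone bit-identically. A run's
configuration (`run_config()`) is plain serializable values, and two runs
from the same config produce identical reports.

## Known limitations

* The modulation depth at a given field strength is an input, not a
  prediction; absolute quantification therefore depends on calibrating
  with the same field and depth as the measurement.
* The lifetime fit assumes the tail past `fit_start` is single-exponential;
  strong background with τ above ~4 ns would bias it and would need
  unmixing.
* Manders coefficients are reported as image statistics only; they carry no
  inference about biological association beyond the scramble baseline.
* The LOD depends on the blank replication scheme; with few blanks the
  blank-SD estimate is itself noisy, which is why detection-limit claims
  are made on the median over many simulated series.
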