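#' Magnetic-field modulation configuration
#'
#' Describes the square-wave magnetic modulation applied during an MMF
#' acquisition: the field toggles between off and on (50% duty, off first),
#' quenching NV\eqn{^-} fluorescence by a fraction `depth_m` while on.
#'
#' @param f_mod Modulation frequency in Hz. The field used 2 Hz.
#' @param field_strength Magnetic flux density in mT (metadata only; the
#'   quench it causes is carried by `depth_m`).
#' @param depth_m Fractional fluorescence quench in `[0, 1)` while the field
#'   is on. Not a measured constant of the instrument; default 0.10, a
#'   typical NV\eqn{^-} quench magnitude at tens of mT.
#' @param sample_rate Samples per second of the time trace; must be at least
#'   `10 * f_mod`.
#' @param duration Acquisition length in seconds. `duration * f_mod` must be
#'   a whole number of modulation periods so the modulation frequency falls
#'   exactly on an FFT bin (no spectral leakage by construction).
#' @return A `modulation_config` list.
#' @examples
#' modulation_config()
#' @export
modulation_config <- function(f_mod = 2, field_strength = 20, depth_m = 0.10,
                              sample_rate = 20, duration = 60) {
  assert_scalar_num(f_mod, "f_mod", 0, strict_lower = TRUE)
  assert_scalar_num(field_strength, "field_strength", 0)
  assert_scalar_num(depth_m, "depth_m", 0)
  if (depth_m >= 1) abort("`depth_m` must be < 1 (got a full or over-quench).")
  assert_scalar_num(sample_rate, "sample_rate", 10 * f_mod)
  assert_scalar_num(duration, "duration", 0, strict_lower = TRUE)
  n_per <- duration * f_mod
  if (abs(n_per - round(n_per)) > 1e-9) {
    abort(sprintf(
      "`duration * f_mod` must be an integer number of periods (got %g).",
      n_per
    ))
  }
  structure(
    list(
      f_mod = f_mod, field_strength = field_strength, depth_m = depth_m,
      sample_rate = sample_rate, duration = duration,
      phase = "square, 50% duty, field-off first"
    ),
    class = "modulation_config"
  )
}

#' @export
print.modulation_config <- function(x, ...) {
  cat(sprintf(
    "<modulation_config> %g Hz square wave, %g mT, depth m = %g, %g Hz sampling, %g s\n",
    x$f_mod, x$field_strength, x$depth_m, x$sample_rate, x$duration
  ))
  invisible(x)
}

#' Emission-spectrum model for FND plus autofluorescence
#'
#' Generative model of the detected far-red emission: an NV\eqn{^-} FND
#' component (zero-phonon line near 638 nm plus broad phonon sideband near
#' 685 nm) riding on a broad, unmodulated autofluorescence background.
#' Both spectral profiles are stored as unit-normalized densities over the
#' wavelength grid; absolute count rates are set by `brightness_per_conc`
#' and `background_level`, both defined at the 685 nm reference channel.
#'
#' @param wavelengths Wavelength grid in nm (default 550-800 nm at 1 nm).
#' @param brightness_per_conc FND count rate at the 685 nm channel, in
#'   counts/s per (ug/mL) of FND.
#' @param background_level Autofluorescence count rate at the 685 nm
#'   channel, counts/s.
#' @param drift_fraction Amplitude of the slow multiplicative drift applied
#'   to the autofluorescence only (sinusoid, period `drift_period`).
#' @param drift_period Drift period in seconds; much longer than the
#'   modulation period, since slow drift is what MMF is designed to reject.
#' @param ref_wavelength Reference wavelength (nm) at which the two rate
#'   parameters are defined; 685 nm, the phonon-sideband detection channel.
#' @return A `spectrum_model` list with `fnd_profile` and `autofluor_profile`
#'   unit-normalized densities on `wavelengths`.
#' @examples
#' m <- spectrum_model()
#' sum(m$fnd_profile * c(diff(m$wavelengths), 1))
#' @export
spectrum_model <- function(wavelengths = seq(550, 800, by = 1),
                           brightness_per_conc = 500,
                           background_level = 1e4,
                           drift_fraction = 0.05,
                           drift_period = 60,
                           ref_wavelength = 685) {
  if (length(wavelengths) < 2 || is.unsorted(wavelengths, strictly = TRUE)) {
    abort("`wavelengths` must be a strictly increasing grid.")
  }
  assert_scalar_num(brightness_per_conc, "brightness_per_conc", 0)
  assert_scalar_num(background_level, "background_level", 0)
  assert_scalar_num(drift_fraction, "drift_fraction", 0)
  assert_scalar_num(drift_period, "drift_period", 0, strict_lower = TRUE)
  if (!any(near(wavelengths, ref_wavelength, 1e-6))) {
    abort("`ref_wavelength` must lie on the wavelength grid.")
  }
  # FND: two-Gaussian mixture, ZPL 638 nm (sigma 5, weight 0.2) +
  # phonon sideband 685 nm (sigma 35, weight 0.8).
  fnd <- 0.2 * stats::dnorm(wavelengths, 638, 5) +
    0.8 * stats::dnorm(wavelengths, 685, 35)
  # Autofluorescence: broad featureless band centred below the FND sideband.
  auto <- stats::dnorm(wavelengths, 600, 80)
  dl <- mean(diff(wavelengths))
  fnd <- fnd / sum(fnd * dl)
  auto <- auto / sum(auto * dl)
  structure(
    list(
      wavelengths = wavelengths, fnd_profile = fnd, autofluor_profile = auto,
      brightness_per_conc = brightness_per_conc,
      background_level = background_level,
      drift_fraction = drift_fraction, drift_period = drift_period,
      ref_wavelength = ref_wavelength
    ),
    class = "spectrum_model"
  )
}

#' Photon-decay model for time gating
#'
#' Two-component fluorescence decay: long-lived FND emission
#' (tau above 15 ns) mixed with short-lived autofluorescence
#' (tau of roughly 1-4 ns), observed through a Gaussian instrument
#' response and binned by a photon-counting board.
#'
#' @param tau_fnd FND fluorescence lifetime, ns (default 17).
#' @param tau_auto Autofluorescence lifetime, ns (default 2.5, mid 1-4 ns).
#' @param fraction_fnd Fraction of detected photons from the FND component.
#' @param irf_sigma Gaussian instrument-response sigma, ns.
#' @param bin_width Histogram bin width, ns.
#' @param n_bins Number of arrival-time bins.
#' @param total_photons Photons to draw per histogram.
#' @return A `decay_model` list.
#' @export
decay_model <- function(tau_fnd = 17, tau_auto = 2.5, fraction_fnd = 0.5,
                        irf_sigma = 0.5, bin_width = 0.2, n_bins = 320,
                        total_photons = 1e5) {
  assert_scalar_num(tau_fnd, "tau_fnd", 0, strict_lower = TRUE)
  assert_scalar_num(tau_auto, "tau_auto", 0, strict_lower = TRUE)
  if (tau_fnd <= tau_auto) {
    abort("`tau_fnd` must exceed `tau_auto` (long-lived FND vs short-lived background).")
  }
  assert_scalar_num(fraction_fnd, "fraction_fnd", 0, 1)
  assert_scalar_num(irf_sigma, "irf_sigma", 0)
  assert_scalar_num(bin_width, "bin_width", 0, strict_lower = TRUE)
  assert_scalar_num(n_bins, "n_bins", 1)
  assert_scalar_num(total_photons, "total_photons", 0)
  structure(
    list(
      tau_fnd = tau_fnd, tau_auto = tau_auto, fraction_fnd = fraction_fnd,
      irf_sigma = irf_sigma, bin_width = bin_width, n_bins = as.integer(n_bins),
      total_photons = total_photons
    ),
    class = "decay_model"
  )
}

#' Synthetic histology-field specification
#'
#' Parameters of a simulated microscopy field: DAPI-stained nuclei placed
#' without overlap, FND puncta confined to the cytoplasmic annulus of
#' labeled cells, and an optional marker channel overlapping a fraction of
#' the labeled cells. Defaults emulate a 20x field of view.
#'
#' @param image_shape Image size in pixels, `c(rows, cols)`.
#' @param pixel_size Pixel size in um.
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_radius Mean nucleus radius, um.
#' @param nucleus_radius_sd SD of nucleus radius, um.
#' @param fnd_labeled_fraction Fraction of cells carrying FND label.
#' @param puncta_per_cell Mean FND puncta per labeled cell.
#' @param cytoplasm_intensity Diffuse FND intensity in the cytoplasm of
#'   labeled cells (endosomal haze underlying the bright puncta).
#' @param marker_positive_fraction Fraction of labeled cells that are
#'   marker-positive (marker channel simulated only when > 0).
#' @param noise_sd Additive Gaussian read-noise SD (intensity units; nucleus
#'   peak intensity is 1).
#' @return A `field_spec` list.
#' @export
field_spec <- function(image_shape = c(256, 256), pixel_size = 0.65,
                       n_nuclei = 25, nucleus_radius = 5,
                       nucleus_radius_sd = 0.5, fnd_labeled_fraction = 1,
                       puncta_per_cell = 12, cytoplasm_intensity = 0.5,
                       marker_positive_fraction = 0, noise_sd = 0.05) {
  if (length(image_shape) != 2 || any(image_shape < 32)) {
    abort("`image_shape` must be two pixel dimensions, each >= 32.")
  }
  assert_scalar_num(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  assert_scalar_num(n_nuclei, "n_nuclei", 0)
  assert_scalar_num(nucleus_radius, "nucleus_radius", 0, strict_lower = TRUE)
  assert_scalar_num(nucleus_radius_sd, "nucleus_radius_sd", 0)
  assert_scalar_num(fnd_labeled_fraction, "fnd_labeled_fraction", 0, 1)
  assert_scalar_num(puncta_per_cell, "puncta_per_cell", 0)
  assert_scalar_num(marker_positive_fraction, "marker_positive_fraction", 0, 1)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  structure(
    list(
      image_shape = as.integer(image_shape), pixel_size = pixel_size,
      n_nuclei = as.integer(n_nuclei), nucleus_radius = nucleus_radius,
      nucleus_radius_sd = nucleus_radius_sd,
      fnd_labeled_fraction = fnd_labeled_fraction,
      puncta_per_cell = puncta_per_cell,
      cytoplasm_intensity = cytoplasm_intensity,
      marker_positive_fraction = marker_positive_fraction,
      noise_sd = noise_sd
    ),
    class = "field_spec"
  )
}

#' Nanodiamond particle model
#'
#' Converts between FND mass and particle count assuming spherical particles
#' of bulk diamond. The per-particle mass is
#' \eqn{\rho \cdot \pi/6 \cdot d^3}.
#'
#' @param diameter Mean particle diameter, nm (default 100).
#' @param density Material density, g/cm^3 (default 3.52, bulk diamond).
#' @return A `particle_model` list with `particle_mass_g` (grams) and
#'   `particle_mass_pg` (picograms).
#' @examples
#' particle_model()$particle_mass_pg
#' @export
particle_model <- function(diameter = 100, density = 3.52) {
  assert_scalar_num(diameter, "diameter", 0, strict_lower = TRUE)
  assert_scalar_num(density, "density", 0, strict_lower = TRUE)
  d_cm <- diameter * 1e-7
  mass_g <- density * pi / 6 * d_cm^3
  structure(
    list(
      diameter = diameter, density = density,
      particle_mass_g = mass_g, particle_mass_pg = mass_g * 1e12
    ),
    class = "particle_model"
  )
}
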