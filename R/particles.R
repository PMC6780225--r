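#' Convert FND mass to particle count
#'
#' Divides a measured FND mass by the per-particle mass of a spherical
#' diamond particle. 49.3 pg of 100 nm particles, for example, corresponds
#' to about 2.7e4 particles.
#'
#' @param mass_pg FND mass in picograms (vectorized, each >= 0).
#' @param particle A [particle_model()].
#' @return A tibble with `mass_pg`, `particles` (exact ratio) and
#'   `particles_2sf` (rounded to 2 significant figures, the precision such
#'   loadings are reported at).
#' @examples
#' mass_to_particles(49.3)
#' @export
mass_to_particles <- function(mass_pg, particle = particle_model()) {
  stopifnot(inherits(particle, "particle_model"))
  if (any(!is.finite(mass_pg)) || any(mass_pg < 0)) {
    abort("`mass_pg` must be finite and non-negative.")
  }
  n <- mass_pg / particle$particle_mass_pg
  tibble(
    mass_pg = mass_pg,
    particles = n,
    particles_2sf = signif(n, 2)
  )
}

#' Per-cell FND loading
#'
#' Total recovered FND mass divided by the number of cells analyzed. With
#' replicate mass measurements the mean loading and its standard error are
#' reported.
#'
#' @param total_mass_pg Total FND mass in pg; a vector is treated as
#'   replicate measurements of the same sample.
#' @param n_cells Number of cells in the analyzed sample (> 0).
#' @return A one-row tibble: `pg_per_cell`, `sem` (NA with a single
#'   measurement), `n_replicates`, `n_cells`.
#' @examples
#' per_cell_loading(4.93e6, 1e5)
#' @export
per_cell_loading <- function(total_mass_pg, n_cells) {
  if (any(!is.finite(total_mass_pg)) || any(total_mass_pg < 0)) {
    abort("`total_mass_pg` must be finite and non-negative.")
  }
  assert_scalar_num(n_cells, "n_cells", 0, strict_lower = TRUE)
  per_cell <- total_mass_pg / n_cells
  tibble(
    pg_per_cell = mean(per_cell),
    sem = if (length(per_cell) >= 2) sd(per_cell) / sqrt(length(per_cell)) else NA_real_,
    n_replicates = length(per_cell),
    n_cells = n_cells
  )
}

#' Spike-recovery rate
#'
#' Mean recovered fraction, in percent, of known spiked amplitudes (or
#' masses/concentrations): `100 * mean(estimated / true)`. Used to validate
#' that MMF quantification survives the tissue-digest background.
#'
#' @param true_values Known spiked values (all > 0).
#' @param estimated_values Paired estimates, same length.
#' @return Recovery in percent (scalar).
#' @examples
#' recovery_rate(c(10, 20), c(9, 18)) # 90
#' @export
recovery_rate <- function(true_values, estimated_values) {
  if (length(true_values) != length(estimated_values)) {
    abort("`true_values` and `estimated_values` must be paired (equal length).")
  }
  if (any(!is.finite(true_values)) || any(true_values <= 0)) {
    abort("all `true_values` must be positive (recovery is undefined at zero spike).")
  }
  100 * mean(estimated_values / true_values)
}
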