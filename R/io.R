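# Readers and writers for the package's on-disk dialects:
# - modulated spectra: TSV (wavelength_nm + one column per timepoint) with a
#   YAML sidecar holding the modulation configuration
# - demodulated spectra and calibration tables: CSV
# - decay histograms: CSV (bin_start_ns, bin_end_ns, counts)
# - image fields / decay stacks: multi-page TIFF with a YAML sidecar

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write / read a modulated spectrum
#'
#' TSV with `wavelength_nm` first and one column per timepoint, plus a YAML
#' sidecar (`<path>.yaml`) carrying the modulation configuration and any
#' simulation ground truth.
#'
#' @param spectrum A `modulated_spectrum`.
#' @param path Output TSV path.
#' @return `write_spectrum_tsv()` returns `path` invisibly;
#'   `read_spectrum_tsv()` returns a `modulated_spectrum`.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "modulated_spectrum"))
  df <- as.data.frame(spectrum$intensities)
  names(df) <- sprintf("t%.6g", spectrum$times)
  df <- cbind(wavelength_nm = spectrum$wavelengths, df)
  readr::write_tsv(df, path)
  cfg <- unclass(spectrum$config)
  truth <- spectrum$truth
  truth$amplitude <- NULL # reconstructable; keep sidecar small
  yaml::write_yaml(list(modulation_config = cfg, truth = truth), sidecar_path(path))
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  side <- yaml::read_yaml(sidecar_path(path))
  cfg <- do.call(modulation_config, side$modulation_config[
    c("f_mod", "field_strength", "depth_m", "sample_rate", "duration")
  ])
  wl <- df$wavelength_nm
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- NULL
  times <- as.numeric(sub("^t", "", names(df)[-1]))
  structure(
    list(
      wavelengths = wl, times = times, intensities = mat, config = cfg,
      truth = side$truth
    ),
    class = "modulated_spectrum"
  )
}

#' Write / read a demodulated spectrum
#'
#' CSV with columns `wavelength_nm, amplitude, noise_floor`.
#'
#' @param dem A `demodulated_spectrum`.
#' @param path CSV path.
#' @export
write_demodulated_csv <- function(dem, path) {
  stopifnot(inherits(dem, "demodulated_spectrum"))
  readr::write_csv(
    tibble(
      wavelength_nm = dem$wavelength, amplitude = dem$amplitude,
      noise_floor = dem$noise_floor
    ),
    path
  )
  invisible(path)
}

#' @rdname write_demodulated_csv
#' @export
read_demodulated_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble(
    wavelength = df$wavelength_nm, amplitude = df$amplitude,
    noise_floor = df$noise_floor
  )
  class(out) <- c("demodulated_spectrum", class(out))
  out
}

#' Write / read a calibration table
#'
#' CSV with header `concentration_ug_per_ml,amplitude,replicate`.
#'
#' @param table Calibration tibble (see [simulate_calibration_series()]).
#' @param path CSV path.
#' @export
write_calibration_csv <- function(table, path) {
  stopifnot(all(c("concentration_ug_per_ml", "amplitude") %in% names(table)))
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a fitted calibration curve as YAML
#'
#' @param cal An `fnd_calibration`.
#' @param path YAML path.
#' @export
write_calibration_yaml <- function(cal, path) {
  stopifnot(inherits(cal, "fnd_calibration"))
  yaml::write_yaml(
    list(
      slope = cal$slope, intercept = cal$intercept,
      residual_sd = cal$residual_sd, blank_sd = cal$blank_sd, lod = cal$lod,
      n = nrow(cal$table), n_blanks = cal$n_blanks
    ),
    path
  )
  invisible(path)
}

#' Write / read a decay histogram
#'
#' CSV with header `bin_start_ns,bin_end_ns,counts`.
#'
#' @param hist A [decay_histogram()].
#' @param path CSV path.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  readr::write_csv(
    tibble(
      bin_start_ns = hist$bin_edges[-length(hist$bin_edges)],
      bin_end_ns = hist$bin_edges[-1],
      counts = hist$counts
    ),
    path
  )
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  decay_histogram(c(df$bin_start_ns, df$bin_end_ns[nrow(df)]), df$counts)
}

# Multi-page float TIFF with a shared intensity scale recorded in the
# sidecar (TIFF pages are stored in [0, 1]).
write_pages_tiff <- function(pages, path, meta) {
  scale <- max(1e-12, max(vapply(pages, max, numeric(1))))
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
    bits.per.sample = 32L
  )
  meta$intensity_scale <- scale
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Write / read an image field as multi-page TIFF
#'
#' One TIFF page per channel; channel names, pixel size and the intensity
#' scale live in a YAML sidecar (`<path>.yaml`).
#'
#' @param field An `image_field`.
#' @param path TIFF path.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "image_field"))
  write_pages_tiff(field$channels, path,
    meta = list(
      kind = "image_field", channels = names(field$channels),
      pixel_size_um = field$pixel_size
    )
  )
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  side <- yaml::read_yaml(sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(pages, function(p) p * side$intensity_scale)
  names(channels) <- side$channels
  structure(
    list(
      channels = channels, pixel_size = side$pixel_size_um,
      spec = NULL, truth = NULL
    ),
    class = "image_field"
  )
}

#' Write / read a per-pixel decay stack as 3-D TIFF
#'
#' One TIFF page per arrival-time bin; bin edges and the intensity scale
#' live in a YAML sidecar.
#'
#' @param stack A `decay_stack`.
#' @param path TIFF path.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "decay_stack"))
  n_bins <- dim(stack$counts)[3]
  pages <- lapply(seq_len(n_bins), function(k) stack$counts[, , k])
  write_pages_tiff(pages, path,
    meta = list(kind = "decay_stack", bin_edges_ns = as.numeric(stack$bin_edges))
  )
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  side <- yaml::read_yaml(sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(
    unlist(pages),
    dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages))
  ) * side$intensity_scale
  structure(
    list(counts = arr, bin_edges = side$bin_edges_ns),
    class = "decay_stack"
  )
}
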