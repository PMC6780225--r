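# Synthetic histology fields with recorded ground truth.

# Hard-core placement: draws centers uniformly (radius-dependent border
# margin) and rejects any candidate closer than 2 * (r_i + r_j) to an
# accepted center, so rendered nuclei stay well separated.
place_nuclei <- function(spec) {
  n <- spec$n_nuclei
  if (n == 0) {
    return(tibble(
      row = numeric(), col = numeric(), radius_um = numeric()
    ))
  }
  shape_um <- spec$image_shape * spec$pixel_size
  rows <- cols <- radii <- numeric(n)
  placed <- 0
  tries <- 0
  max_tries <- 400 * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1
    r <- max(spec$nucleus_radius / 4,
      rnorm(1, spec$nucleus_radius, spec$nucleus_radius_sd))
    margin <- 2 * r
    if (2 * margin >= min(shape_um)) next
    y <- runif(1, margin, shape_um[1] - margin)
    x <- runif(1, margin, shape_um[2] - margin)
    ok <- placed == 0 || all(
      sqrt((rows[seq_len(placed)] - y)^2 + (cols[seq_len(placed)] - x)^2) >=
        2 * (radii[seq_len(placed)] + r)
    )
    if (ok) {
      placed <- placed + 1
      rows[placed] <- y
      cols[placed] <- x
      radii[placed] <- r
    }
  }
  if (placed < n) {
    abort(sprintf(
      "could only place %d of %d non-overlapping nuclei in a %g x %g um field; reduce density or nucleus size.",
      placed, n, shape_um[1], shape_um[2]
    ))
  }
  tibble(row = rows, col = cols, radius_um = radii)
}

# Add an isotropic Gaussian blob (amplitude `a`, sd `sigma`, all in pixel
# units) to an image, evaluating only a local window for speed.
add_blob <- function(img, row, col, sigma, a) {
  h <- ceiling(4 * sigma)
  r0 <- max(1, floor(row - h)); r1 <- min(nrow(img), ceiling(row + h))
  c0 <- max(1, floor(col - h)); c1 <- min(ncol(img), ceiling(col + h))
  if (r0 > r1 || c0 > c1) return(img)
  ys <- r0:r1
  xs <- c0:c1
  g <- exp(-outer((ys - row)^2, (xs - col)^2, `+`) / (2 * sigma^2))
  img[ys, xs] <- img[ys, xs] + a * g
  img
}

#' Simulate a multichannel histology field
#'
#' Renders a DAPI channel of non-overlapping Gaussian-profile nuclei, an
#' FND channel with diffuse cytoplasmic signal plus bright puncta confined
#' to the perinuclear annulus of labeled cells, and (when
#' `marker_positive_fraction > 0`) a marker channel overlapping a fraction
#' of the labeled cells. Additive Gaussian read noise is applied to every
#' channel and intensities are clipped at zero. Ground-truth centers,
#' radii and labels are returned in `truth`.
#'
#' @param spec A [field_spec()].
#' @param seed Integer seed; identical seeds give identical fields.
#' @return An `image_field`: named `channels` (matrices `dapi`, `fnd`, and
#'   optionally `marker`), `pixel_size` (um), the `spec`, and a `truth`
#'   tibble (one row per nucleus: position in px and um, radius, `labeled`,
#'   `marker_positive`).
#' @examples
#' fld <- simulate_field(field_spec(n_nuclei = 10), seed = 1)
#' names(fld$channels)
#' @export
simulate_field <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "field_spec"))
  with_seed(seed, {
    centers <- place_nuclei(spec)
    n <- nrow(centers)
    labeled <- runif(n) < spec$fnd_labeled_fraction
    marker_pos <- labeled & runif(n) < spec$marker_positive_fraction

    px <- spec$pixel_size
    dims <- spec$image_shape
    dapi <- matrix(0, dims[1], dims[2])
    fnd <- matrix(0, dims[1], dims[2])
    marker <- matrix(0, dims[1], dims[2])

    for (i in seq_len(n)) {
      ry <- centers$row[i] / px
      cx <- centers$col[i] / px
      r_px <- centers$radius_um[i] / px
      dapi <- add_blob(dapi, ry, cx, sigma = r_px / 2, a = 1)
      if (labeled[i]) {
        # diffuse endosomal haze over the whole cell body
        fnd <- add_blob(fnd, ry, cx, sigma = 1.5 * r_px, a = spec$cytoplasm_intensity)
        n_p <- rpois(1, spec$puncta_per_cell)
        if (n_p > 0) {
          # puncta uniform in the cytoplasmic annulus (r, 2r]
          rad <- sqrt(runif(n_p, r_px^2, (2 * r_px)^2))
          ang <- runif(n_p, 0, 2 * pi)
          for (j in seq_len(n_p)) {
            fnd <- add_blob(fnd, ry + rad[j] * sin(ang[j]),
              cx + rad[j] * cos(ang[j]),
              sigma = 1.5, a = 0.6)
          }
        }
      }
      if (marker_pos[i]) {
        marker <- add_blob(marker, ry, cx, sigma = 1.2 * r_px, a = 0.8)
      }
    }

    channels <- list(dapi = dapi, fnd = fnd)
    if (spec$marker_positive_fraction > 0) channels$marker <- marker
    if (spec$noise_sd > 0) {
      channels <- lapply(channels, function(ch) {
        pmax(ch + matrix(rnorm(length(ch), 0, spec$noise_sd), nrow(ch)), 0)
      })
    }

    structure(
      list(
        channels = channels, pixel_size = px, spec = spec,
        truth = tibble(
          nucleus = seq_len(n),
          row_px = centers$row / px, col_px = centers$col / px,
          row_um = centers$row, col_um = centers$col,
          radius_um = centers$radius_um,
          labeled = labeled, marker_positive = marker_pos
        )
      ),
      class = "image_field"
    )
  })
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf(
    "<image_field> %d x %d px (%.2g um/px), channels: %s, %d nuclei (truth)\n",
    nrow(x$channels[[1]]), ncol(x$channels[[1]]), x$pixel_size,
    paste(names(x$channels), collapse = ", "), nrow(x$truth)
  ))
  invisible(x)
}

#' Plot a simulated or loaded image field
#'
#' Raster view of each channel, faceted, on a shared coordinate system.
#'
#' @param object An `image_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.image_field <- function(object, ...) {
  df <- purrr::imap_dfr(object$channels, function(ch, nm) {
    tibble(
      channel = nm,
      row = rep(seq_len(nrow(ch)), times = ncol(ch)),
      col = rep(seq_len(ncol(ch)), each = nrow(ch)),
      intensity = as.vector(ch)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
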