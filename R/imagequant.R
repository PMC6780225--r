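# Field-based cell quantification: nucleus counting, FND-positive cell
# detection, Manders colocalization, per-section summaries.

# Otsu threshold on an arbitrary-range non-negative image, returned on the
# original intensity scale. Constant images have no threshold (NA).
otsu_threshold <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng)) || diff(rng) == 0) {
    return(NA_real_)
  }
  xn <- (x - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1), levels = 256)
  rng[1] + th * diff(rng)
}

#' Count DAPI-stained nuclei in a field
#'
#' Reproducible counting operator: Gaussian smoothing at half the expected
#' nucleus radius, global Otsu threshold, connected components, and a
#' minimum-area filter of `pi * (radius/2)^2` pixels that removes debris
#' smaller than half a nucleus. The simulator places nuclei without
#' overlap, so no watershed splitting is applied by default; set
#' `watershed = TRUE` for real tissue where nuclei touch.
#'
#' @param field An `image_field` with a `dapi` channel.
#' @param expected_radius Expected nucleus radius in um (default 5).
#' @param watershed Apply distance-transform watershed splitting before
#'   filtering (for touching nuclei on real data).
#' @return A `nucleus_count`: `n_nuclei`, integer `labels` matrix, and a
#'   `nuclei` tibble (label, centroid in px, area in px and um^2).
#' @examples
#' fld <- simulate_field(field_spec(n_nuclei = 8, noise_sd = 0), seed = 1)
#' count_nuclei(fld)$n_nuclei
#' @export
count_nuclei <- function(field, expected_radius = 5, watershed = FALSE) {
  stopifnot(inherits(field, "image_field"))
  if (is.null(field$channels$dapi)) abort("field has no `dapi` channel.")
  img <- field$channels$dapi
  r_px <- expected_radius / field$pixel_size

  empty <- function(msg) {
    warn(msg)
    structure(
      list(
        n_nuclei = 0L, labels = matrix(0L, nrow(img), ncol(img)),
        nuclei = tibble(
          label = integer(), row_px = numeric(), col_px = numeric(),
          area_px = numeric(), area_um2 = numeric()
        )
      ),
      class = "nucleus_count"
    )
  }
  if (diff(range(img)) == 0) {
    return(empty("DAPI channel is constant; no nuclei to count."))
  }

  sm <- EBImage::gblur(EBImage::Image(img / max(img)), sigma = 0.5 * r_px)
  th <- otsu_threshold(as.matrix(sm))
  mask <- as.matrix(sm) > th
  if (!any(mask)) {
    return(empty("nothing above the Otsu threshold; count is 0."))
  }
  lab <- if (watershed) {
    EBImage::watershed(EBImage::distmap(EBImage::Image(mask)), tolerance = 1)
  } else {
    EBImage::bwlabel(EBImage::Image(mask))
  }
  lab <- as.matrix(lab)

  min_area <- pi * (0.5 * r_px)^2
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  relab <- matrix(0L, nrow(lab), ncol(lab))
  nuclei <- purrr::map_dfr(seq_along(keep), function(i) {
    sel <- lab == keep[i]
    relab[sel] <<- i
    idx <- which(sel, arr.ind = TRUE)
    tibble(
      label = i,
      row_px = mean(idx[, 1]), col_px = mean(idx[, 2]),
      area_px = nrow(idx), area_um2 = nrow(idx) * field$pixel_size^2
    )
  })
  structure(
    list(n_nuclei = length(keep), labels = relab, nuclei = nuclei),
    class = "nucleus_count"
  )
}

#' @export
print.nucleus_count <- function(x, ...) {
  cat(sprintf("<nucleus_count> %d nuclei\n", x$n_nuclei))
  invisible(x)
}

#' Detect FND-labeled cells around counted nuclei
#'
#' A nucleus is FND-positive when the mean FND intensity in its
#' perinuclear annulus — between one and two equivalent nucleus radii from
#' the centroid — exceeds the FND channel's global Otsu threshold. Pass the
#' time-gated FND channel where available; gating is what makes the FND
#' signal stand clear of tissue autofluorescence.
#'
#' @param field An `image_field` with an `fnd` channel.
#' @param nuclei A `nucleus_count` from [count_nuclei()] on the same field.
#' @return A tibble, one row per nucleus: `label`, `mean_fnd`, `threshold`,
#'   `fnd_positive`. `sum(out$fnd_positive)` is the FND-positive count.
#' @examples
#' fld <- simulate_field(field_spec(n_nuclei = 8, noise_sd = 0), seed = 1)
#' nc <- count_nuclei(fld)
#' sum(detect_fnd_cells(fld, nc)$fnd_positive)
#' @export
detect_fnd_cells <- function(field, nuclei) {
  stopifnot(inherits(field, "image_field"), inherits(nuclei, "nucleus_count"))
  if (is.null(field$channels$fnd)) abort("field has no `fnd` channel.")
  fnd <- field$channels$fnd
  if (nuclei$n_nuclei == 0) {
    return(tibble(
      label = integer(), mean_fnd = numeric(), threshold = numeric(),
      fnd_positive = logical()
    ))
  }
  th <- otsu_threshold(fnd)
  rows <- matrix(seq_len(nrow(fnd)), nrow(fnd), ncol(fnd))
  cols <- matrix(seq_len(ncol(fnd)), nrow(fnd), ncol(fnd), byrow = TRUE)
  purrr::map_dfr(seq_len(nuclei$n_nuclei), function(i) {
    nb <- nuclei$nuclei[i, ]
    r_eq <- sqrt(nb$area_px / pi)
    d2 <- (rows - nb$row_px)^2 + (cols - nb$col_px)^2
    ann <- d2 > r_eq^2 & d2 <= (2 * r_eq)^2
    m <- mean(fnd[ann])
    tibble(
      label = nb$label, mean_fnd = m, threshold = th,
      fnd_positive = !is.na(th) && m > th
    )
  })
}

#' Manders colocalization coefficients
#'
#' Split Manders coefficients between two channels with Otsu-determined
#' thresholds: `M1` is the fraction of channel-A intensity (over A's
#' above-threshold pixels) that lies where channel B is also above its
#' threshold; `M2` is the symmetric quantity for B. Both lie in `[0, 1]`
#' and swap under channel exchange. Pair with [scramble_control()] to judge
#' whether an observed value exceeds chance overlap.
#'
#' @param field An `image_field`.
#' @param ch_a,ch_b Channel names (e.g. `"fnd"`, `"marker"`).
#' @return A one-row tibble: `m1`, `m2`, `threshold_a`, `threshold_b`,
#'   `undefined` (TRUE when a channel is constant, with `m1`/`m2` NA).
#' @export
colocalization <- function(field, ch_a = "fnd", ch_b = "marker") {
  stopifnot(inherits(field, "image_field"))
  for (ch in c(ch_a, ch_b)) {
    if (is.null(field$channels[[ch]])) abort(sprintf("field has no `%s` channel.", ch))
  }
  a <- field$channels[[ch_a]]
  b <- field$channels[[ch_b]]
  ta <- otsu_threshold(a)
  tb <- otsu_threshold(b)
  if (is.na(ta) || is.na(tb)) {
    warn("a channel is constant; Manders coefficients are undefined.")
    return(tibble(
      m1 = NA_real_, m2 = NA_real_, threshold_a = ta, threshold_b = tb,
      undefined = TRUE
    ))
  }
  a_on <- a > ta
  b_on <- b > tb
  m1 <- if (any(a_on)) sum(a[a_on & b_on]) / sum(a[a_on]) else NA_real_
  m2 <- if (any(b_on)) sum(b[a_on & b_on]) / sum(b[b_on]) else NA_real_
  tibble(m1 = m1, m2 = m2, threshold_a = ta, threshold_b = tb, undefined = FALSE)
}

#' Block-scramble control for colocalization
#'
#' Returns a copy of the field with one channel's blocks randomly permuted,
#' destroying spatial correspondence while preserving the channel's
#' intensity content. Colocalization of the scrambled field estimates the
#' chance-overlap baseline.
#'
#' @param field An `image_field`.
#' @param channel Channel to scramble.
#' @param block_px Block edge in pixels (default 32; about the cell scale).
#' @param seed Integer seed.
#' @return The field with the channel scrambled.
#' @export
scramble_control <- function(field, channel = "marker", block_px = 32,
                             seed = NULL) {
  stopifnot(inherits(field, "image_field"))
  ch <- field$channels[[channel]]
  if (is.null(ch)) abort(sprintf("field has no `%s` channel.", channel))
  nr <- floor(nrow(ch) / block_px)
  nc <- floor(ncol(ch) / block_px)
  if (nr * nc < 2) abort("image too small for the requested block size.")
  out <- ch
  blocks <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  perm <- with_seed(seed, sample(nrow(blocks)))
  for (k in seq_len(nrow(blocks))) {
    src <- blocks[perm[k], ]
    dst <- blocks[k, ]
    out[(dst$i - 1) * block_px + seq_len(block_px),
        (dst$j - 1) * block_px + seq_len(block_px)] <-
      ch[(src$i - 1) * block_px + seq_len(block_px),
         (src$j - 1) * block_px + seq_len(block_px)]
  }
  field$channels[[channel]] <- out
  field
}

#' Quantify one field end to end
#'
#' Convenience wrapper producing a single per-field record: nucleus count,
#' FND-positive count, and (when a marker channel is present) Manders
#' coefficients.
#'
#' @param field An `image_field`.
#' @param expected_radius Passed to [count_nuclei()].
#' @param field_id Identifier recorded in the output row.
#' @return A one-row tibble: `field_id`, `n_nuclei`, `n_fnd_positive`,
#'   `coloc_m1`, `coloc_m2`.
#' @export
quantify_field <- function(field, expected_radius = 5, field_id = 1L) {
  nc <- count_nuclei(field, expected_radius = expected_radius)
  det <- detect_fnd_cells(field, nc)
  m1 <- m2 <- NA_real_
  if (!is.null(field$channels$marker)) {
    cl <- colocalization(field, "fnd", "marker")
    m1 <- cl$m1
    m2 <- cl$m2
  }
  tibble(
    field_id = field_id,
    n_nuclei = nc$n_nuclei,
    n_fnd_positive = sum(det$fnd_positive),
    coloc_m1 = m1, coloc_m2 = m2
  )
}

#' Summarize per-field quantifications for a section
#'
#' Mean and standard error of each per-field metric over the (typically
#' six) random fields counted per section.
#'
#' @param quants A tibble of per-field rows, e.g. from [quantify_field()];
#'   at least 2 fields (SEM is undefined otherwise).
#' @return A tibble with one row per metric: `metric`, `mean`, `sem`,
#'   `n_fields`.
#' @examples
#' q <- tibble::tibble(field_id = 1:2, n_nuclei = c(8, 12))
#' summarize_fields(q)
#' @export
summarize_fields <- function(quants) {
  quants <- as_tibble(quants)
  if (nrow(quants) < 2) {
    abort("at least 2 fields are required (SEM is undefined for one field).")
  }
  metrics <- setdiff(
    names(quants)[vapply(quants, is.numeric, logical(1))], "field_id"
  )
  purrr::map_dfr(metrics, function(m) {
    v <- quants[[m]]
    v <- v[is.finite(v)]
    tibble(
      metric = m,
      mean = mean(v),
      sem = sd(v) / sqrt(length(v)),
      n_fields = length(v)
    )
  })
}
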