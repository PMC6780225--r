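# Forward simulators for photon arrival-time data.

#' Construct a photon-decay histogram
#'
#' Container for photon counts per arrival-time bin, as produced by a
#' time-correlated photon-counting board. Usually created by
#' [simulate_decay_histogram()] or [read_histogram_csv()].
#'
#' @param bin_edges Strictly increasing bin edges, ns (length `n_bins + 1`).
#' @param counts Photon counts per bin (non-negative, length `n_bins`).
#' @param meta Optional provenance list; simulators store the generating
#'   [decay_model()] and per-component counts here.
#' @return A `decay_histogram` object.
#' @export
decay_histogram <- function(bin_edges, counts, meta = NULL) {
  if (length(bin_edges) != length(counts) + 1) {
    abort("`bin_edges` must have one more element than `counts`.")
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort("`bin_edges` must be strictly increasing.")
  }
  if (any(counts < 0)) abort("`counts` must be non-negative.")
  structure(
    list(bin_edges = bin_edges, counts = counts, meta = meta),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf(
    "<decay_histogram> %d bins over %g-%g ns, %g photons\n",
    length(x$counts), min(x$bin_edges), max(x$bin_edges), sum(x$counts)
  ))
  invisible(x)
}

#' Simulate a photon-decay histogram
#'
#' Draws photon arrival times from the two-component exponential mixture of
#' a [decay_model()] (long-lived FND emission plus short-lived
#' autofluorescence), adds Gaussian instrument-response jitter to each
#' arrival in continuous time, and bins the result. Photons jittered
#' outside the histogram range are dropped, as a real board would. The
#' per-component counts are kept as ground truth.
#'
#' @param model A [decay_model()].
#' @param seed Integer seed.
#' @return A [decay_histogram()] whose `meta` holds the model, the seed, and
#'   a `component_counts` matrix (columns `fnd`, `auto`).
#' @examples
#' h <- simulate_decay_histogram(decay_model(total_photons = 1e4), seed = 1)
#' sum(h$counts)
#' @export
simulate_decay_histogram <- function(model, seed = NULL) {
  stopifnot(inherits(model, "decay_model"))
  t_max <- model$n_bins * model$bin_width
  if (t_max < 3 * model$tau_fnd) {
    warn(sprintf(
      "histogram range (%g ns) is shorter than 3 tau_fnd (%g ns); tail truncation will bias lifetime estimates.",
      t_max, 3 * model$tau_fnd
    ))
  }
  edges <- seq(0, t_max, by = model$bin_width)
  n <- round(model$total_photons)
  if (n == 0) {
    return(decay_histogram(edges, rep(0, model$n_bins),
      meta = list(
        model = model, seed = seed,
        component_counts = matrix(0, model$n_bins, 2,
          dimnames = list(NULL, c("fnd", "auto"))
        )
      )
    ))
  }
  sim <- with_seed(seed, {
    is_fnd <- runif(n) < model$fraction_fnd
    tau <- ifelse(is_fnd, model$tau_fnd, model$tau_auto)
    t <- rexp(n, rate = 1 / tau)
    if (model$irf_sigma > 0) t <- t + rnorm(n, 0, model$irf_sigma)
    list(t = t, is_fnd = is_fnd)
  })
  keep <- sim$t >= 0 & sim$t < t_max
  bin <- findInterval(sim$t[keep], edges, rightmost.closed = TRUE)
  comp <- matrix(0, model$n_bins, 2, dimnames = list(NULL, c("fnd", "auto")))
  tb_f <- tabulate(bin[sim$is_fnd[keep]], nbins = model$n_bins)
  tb_a <- tabulate(bin[!sim$is_fnd[keep]], nbins = model$n_bins)
  comp[, "fnd"] <- tb_f
  comp[, "auto"] <- tb_a
  decay_histogram(edges, tb_f + tb_a,
    meta = list(model = model, seed = seed, component_counts = comp)
  )
}

# CDF of an exponential decay (lifetime tau) observed through a Gaussian
# IRF of width sigma (exponentially modified Gaussian with mu = 0).
emg_cdf <- function(t, tau, sigma) {
  if (sigma == 0) {
    return(ifelse(t < 0, 0, 1 - exp(-t / tau)))
  }
  stats::pnorm(t / sigma) -
    exp(sigma^2 / (2 * tau^2) - t / tau + stats::pnorm(t / sigma - sigma / tau, log.p = TRUE))
}

# Expected bin probabilities for one decay component.
decay_bin_probs <- function(edges, tau, sigma) {
  diff(emg_cdf(edges, tau, sigma))
}

#' Simulate a per-pixel photon-decay stack
#'
#' Generates the input of [gated_image()]: a 3-D array of photon counts
#' (row, column, arrival-time bin). Each pixel's expected decay is the
#' mixture of the FND and autofluorescence components of `model`, with the
#' pixel's FND fraction taken from `fnd_fraction`; counts are Poisson.
#'
#' @param fnd_fraction Matrix in `[0, 1]`: per-pixel fraction of expected
#'   photons coming from the FND component (e.g. bright puncta on a zero
#'   background).
#' @param model A [decay_model()] supplying lifetimes, IRF and binning.
#' @param photons_per_pixel Expected total photons in each pixel.
#' @param seed Integer seed.
#' @return A `decay_stack`: list with `counts` (3-D array), `bin_edges`, and
#'   the generating parameters.
#' @examples
#' f <- matrix(0, 8, 8); f[4, 4] <- 1
#' st <- simulate_decay_stack(f, decay_model(n_bins = 64), 200, seed = 1)
#' dim(st$counts)
#' @export
simulate_decay_stack <- function(fnd_fraction, model = decay_model(),
                                 photons_per_pixel = 500, seed = NULL) {
  stopifnot(is.matrix(fnd_fraction), inherits(model, "decay_model"))
  if (any(fnd_fraction < 0 | fnd_fraction > 1)) {
    abort("`fnd_fraction` entries must lie in [0, 1].")
  }
  assert_scalar_num(photons_per_pixel, "photons_per_pixel", 0)
  edges <- seq(0, model$n_bins * model$bin_width, by = model$bin_width)
  p_f <- decay_bin_probs(edges, model$tau_fnd, model$irf_sigma)
  p_a <- decay_bin_probs(edges, model$tau_auto, model$irf_sigma)
  npx <- length(fnd_fraction)
  # expected counts: npx x n_bins
  mu <- photons_per_pixel *
    (as.vector(fnd_fraction) %o% p_f + (1 - as.vector(fnd_fraction)) %o% p_a)
  counts <- with_seed(seed, rpois(length(mu), mu))
  arr <- array(counts, dim = c(nrow(fnd_fraction), ncol(fnd_fraction), model$n_bins))
  structure(
    list(
      counts = arr, bin_edges = edges, model = model,
      photons_per_pixel = photons_per_pixel,
      truth = list(fnd_fraction = fnd_fraction, seed = seed)
    ),
    class = "decay_stack"
  )
}
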