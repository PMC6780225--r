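# Nucleus counting, FND-positive detection, colocalization, summaries.

make_field <- function(channels, pixel_size = 0.65) {
  structure(
    list(channels = channels, pixel_size = pixel_size, truth = NULL),
    class = "image_field"
  )
}

test_that("noiseless fields are counted exactly and blanks give zero", {
  fld <- simulate_field(field_spec(n_nuclei = 25, noise_sd = 0), seed = 71)
  nc <- count_nuclei(fld)
  expect_equal(nc$n_nuclei, 25)
  expect_equal(nrow(nc$nuclei), 25)

  blank <- make_field(list(dapi = matrix(0, 64, 64)))
  expect_warning(nc0 <- count_nuclei(blank), "constant")
  expect_equal(nc0$n_nuclei, 0)
})

test_that("counting is invariant to global intensity scaling", {
  fld <- simulate_field(field_spec(), seed = 72)
  n1 <- count_nuclei(fld)$n_nuclei
  fld$channels$dapi <- fld$channels$dapi * 7.3
  expect_equal(count_nuclei(fld)$n_nuclei, n1)
})

test_that("counts at default noise are within one nucleus of the truth", {
  errs <- vapply(1:12, function(s) {
    fld <- simulate_field(field_spec(), seed = 700 + s)
    abs(count_nuclei(fld)$n_nuclei - nrow(fld$truth))
  }, numeric(1))
  expect_true(all(errs <= 1))
})

test_that("density recovery is unbiased on noiseless fields across densities", {
  for (n in c(10, 25, 40)) {
    fld <- simulate_field(field_spec(n_nuclei = n, noise_sd = 0), seed = 80 + n)
    expect_equal(count_nuclei(fld)$n_nuclei, n)
  }
})

test_that("FND-positive detection recovers the labeled fraction", {
  fld1 <- simulate_field(field_spec(fnd_labeled_fraction = 1, noise_sd = 0), seed = 73)
  nc1 <- count_nuclei(fld1)
  expect_equal(sum(detect_fnd_cells(fld1, nc1)$fnd_positive), nc1$n_nuclei)

  fld0 <- simulate_field(field_spec(fnd_labeled_fraction = 0), seed = 74)
  nc0 <- count_nuclei(fld0)
  expect_equal(sum(detect_fnd_cells(fld0, nc0)$fnd_positive), 0)

  fracs <- vapply(1:20, function(s) {
    fld <- simulate_field(field_spec(fnd_labeled_fraction = 0.5), seed = 7000 + s)
    nc <- count_nuclei(fld)
    sum(detect_fnd_cells(fld, nc)$fnd_positive) / nc$n_nuclei
  }, numeric(1))
  expect_within(mean(fracs), 0.5, 0.1)

  no_fnd <- make_field(list(dapi = fld1$channels$dapi))
  expect_error(detect_fnd_cells(no_fnd, nc1), "fnd")
})

test_that("Manders coefficients hit their limit cases exactly", {
  a <- matrix(0, 64, 64)
  a[10:20, 10:20] <- 1
  same <- make_field(list(fnd = a, marker = a))
  cl <- colocalization(same, "fnd", "marker")
  expect_equal(cl$m1, 1)
  expect_equal(cl$m2, 1)

  b <- matrix(0, 64, 64)
  b[40:50, 40:50] <- 1
  disjoint <- make_field(list(fnd = a, marker = b))
  cd <- colocalization(disjoint, "fnd", "marker")
  expect_equal(cd$m1, 0)
  expect_equal(cd$m2, 0)

  const <- make_field(list(fnd = a, marker = matrix(0, 64, 64)))
  expect_warning(cu <- colocalization(const, "fnd", "marker"), "undefined")
  expect_true(cu$undefined)
})

test_that("M1 and M2 swap under channel exchange and stay in [0, 1]", {
  fld <- simulate_field(field_spec(marker_positive_fraction = 0.8), seed = 75)
  ab <- colocalization(fld, "fnd", "marker")
  ba <- colocalization(fld, "marker", "fnd")
  expect_equal(ab$m1, ba$m2)
  expect_equal(ab$m2, ba$m1)
  expect_true(all(c(ab$m1, ab$m2) >= 0 & c(ab$m1, ab$m2) <= 1))
})

test_that("true marker overlap exceeds the block-scramble control", {
  for (s in 1:8) {
    fld <- simulate_field(field_spec(marker_positive_fraction = 0.8), seed = 7600 + s)
    m_true <- colocalization(fld, "fnd", "marker")$m1
    scr <- scramble_control(fld, "marker", seed = s)
    m_scr <- colocalization(scr, "fnd", "marker")$m1
    expect_gt(m_true, m_scr)
  }
})

test_that("per-section summaries give mean and SEM per metric", {
  q <- tibble::tibble(field_id = 1:6, n_nuclei = rep(10, 6))
  s <- summarize_fields(q)
  expect_equal(s$mean[s$metric == "n_nuclei"], 10)
  expect_equal(s$sem[s$metric == "n_nuclei"], 0)

  s2 <- summarize_fields(tibble::tibble(field_id = 1:2, n_nuclei = c(8, 12)))
  expect_equal(s2$mean, 10)
  expect_equal(s2$sem, 2)

  expect_error(summarize_fields(tibble::tibble(field_id = 1, n_nuclei = 5)), "2 fields")
})

test_that("a 2:1 density difference between groups is recovered within 20%", {
  section_mean <- function(n_nuclei, seed) {
    q <- purrr::map_dfr(1:2, function(f) {
      fld <- simulate_field(
        field_spec(image_shape = c(128, 128), n_nuclei = n_nuclei),
        seed = seed * 10 + f
      )
      quantify_field(fld, field_id = f)
    })
    summarize_fields(q)$mean[summarize_fields(q)$metric == "n_nuclei"]
  }
  g_high <- vapply(1:5, function(s) section_mean(8, 900 + s), numeric(1))
  g_low <- vapply(1:5, function(s) section_mean(4, 950 + s), numeric(1))
  ratio <- mean(g_high) / mean(g_low)
  expect_within(ratio, 2, 0.4)
})
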