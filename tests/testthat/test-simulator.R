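test_that("mixture composition is the concentration-weighted reference sum", {
  lib <- tiny_library(3, 2000)
  a <- length(lib$analytes)
  tsp <- lib$references$TSP$intensity

  # empty mixture with the internal standard is 0.3 x TSP
  mix0 <- compose_mixture(lib, rep(0, a))
  expect_equal(mix0$intensity, 0.3 * tsp)
  expect_equal(mix0$tsp_mM, 0.3)

  # single analyte at 1 mM without TSP equals its reference exactly
  c1 <- c(1, 0, 0)
  m1 <- compose_mixture(lib, c1, include_tsp = FALSE)
  expect_equal(m1$intensity, lib$references[[lib$analytes[1]]]$intensity)

  # linearity: doubling concentrations doubles the analyte part
  cc <- c(0.4, 2.5, 7)
  ma <- compose_mixture(lib, cc)
  mb <- compose_mixture(lib, 2 * cc)
  expect_equal(mb$intensity - 0.3 * tsp, 2 * (ma$intensity - 0.3 * tsp))

  expect_error(compose_mixture(lib, c(-1, 0, 0)), "non-negative")
  expect_error(compose_mixture(lib, c(1, 2)), "expected 3")
})

test_that("NNLS on the reference library inverts the noise-free simulator", {
  lib <- tiny_library(5, 3000)
  ds <- build_dataset(lib, 6, sampler = conc_sampler("uniform"),
                      augmentation = augmentation_config(enabled = FALSE),
                      seed = 31)
  est <- nnls_quantify(ds, lib)
  expect_lt(max(abs(est - ds$truth) / ds$truth), 1e-3)
})

test_that("dataset generation is reproducible and correctly normalised", {
  lib <- tiny_library(4, 1500)
  d1 <- build_dataset(lib, 12, seed = 32)
  d2 <- build_dataset(lib, 12, seed = 32)
  expect_identical(d1$spectra, d2$spectra)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$record$lb_hz, d2$record$lb_hz)
  d3 <- build_dataset(lib, 12, seed = 33)
  expect_false(identical(d1$spectra, d3$spectra))

  # global maximum is exactly 1; relative intensities unchanged
  expect_equal(max(d1$spectra), 1)
  raw <- d1$spectra * d1$norm_constant
  i <- which.max(raw[1, ])
  expect_equal(raw[1, ] / raw[1, i], d1$spectra[1, ] / d1$spectra[1, i])

  # all-present scheme: strictly positive ground truth, TSP fixed
  expect_true(all(d1$truth > 0))
  expect_true(all(d1$tsp_mM == 0.3))
})

test_that("the 80:20 split is disjoint, exhaustive, and sized correctly", {
  lib <- tiny_library(3, 800)
  ds <- build_dataset(lib, 50, seed = 34)
  expect_length(ds$split$train, 40)
  expect_length(ds$split$validation, 10)
  expect_length(intersect(ds$split$train, ds$split$validation), 0)
  expect_setequal(c(ds$split$train, ds$split$validation), 1:50)
  # the protocol sizes: 80% of 20,000 is 16,000
  expect_identical(round(0.8 * 20000), 16000)
})

test_that("realised augmentation parameters respect their configured ranges", {
  lib <- tiny_library(4, 1500)
  ds <- build_dataset(lib, 300, scheme = "half50", seed = 35)
  rec <- ds$record
  expect_true(all(rec$lb_hz >= 0 & rec$lb_hz <= 1))
  expect_true(all(rec$noise_fraction >= 0.30 & rec$noise_fraction <= 1.15))
  expect_true(all(rec$n_interference %in% 0:3))
  shifts <- unlist(rec$shift_ppb)
  expect_true(all(abs(shifts) <= 3.4))
  tsp_peak <- 0.3 * max(lib$references$TSP$intensity)
  expect_true(all(abs(rec$baseline) <= 0.056 * tsp_peak))
  # leave-out recorded as zero concentration
  expect_true(any(ds$truth == 0))
  expect_true(all(ds$truth >= 0))
})

test_that("normalisation modes: own maximum or an external constant", {
  lib <- tiny_library(3, 800)
  ds <- build_dataset(lib, 8, seed = 36, normalize = FALSE)
  expect_equal(ds$norm_constant, 1)
  dn <- normalize_dataset(ds)
  expect_equal(max(dn$spectra), 1)
  # normalising a test set by the training constant
  dt <- build_dataset(lib, 4, seed = 37, normalize = FALSE)
  dte <- normalize_dataset(dt, constant = dn$norm_constant)
  expect_equal(dte$spectra * dte$norm_constant, dt$spectra)
  bad <- ds
  bad$spectra[] <- 0
  expect_error(normalize_dataset(bad), "not positive")
})

test_that("mean SNR is ordered with field strength on matched mixtures", {
  snr_at <- function(field) {
    lib <- default_library(4, field_strength = field, seed = 40,
                           grid = tiny_grid(4000))
    ds <- build_dataset(lib, 20, seed = 41)
    mean(vapply(1:20, function(i) {
      as.numeric(compute_snr(ds$spectra[i, ], ds$grid))
    }, numeric(1)))
  }
  s100 <- snr_at(100)
  s400 <- snr_at(400)
  s800 <- snr_at(800)
  expect_lt(s100, s400)
  expect_lt(s400, s800)
})

test_that("datasets round-trip through the on-disk text format", {
  lib <- tiny_library(3, 600)
  ds <- build_dataset(lib, 10, seed = 42)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- read_dataset(dir)
  expect_equal(back$spectra, ds$spectra, tolerance = 1e-6)
  expect_equal(back$truth, unname(ds$truth), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$split$train, ds$split$train)
  expect_equal(back$norm_constant, ds$norm_constant)
  expect_identical(back$analytes, ds$analytes)
})

test_that("truth_table exposes split, source and TSP per spectrum", {
  lib <- tiny_library(3, 600)
  ds <- build_dataset(lib, 10, seed = 43)
  tt <- truth_table(ds)
  expect_identical(nrow(tt), 10L)
  expect_true(all(tt$TSP == 0.3))
  expect_identical(sum(tt$split == "train"), 8L)
  expect_true(all(lib$analytes %in% names(tt)))
})
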