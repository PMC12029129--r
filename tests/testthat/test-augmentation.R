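test_that("line broadening preserves the integral and adds Lorentzian width", {
  g <- ppm_grid(-0.32, 10.21, 46000)
  ref <- synth_reference("s", list(multiplet(5, 1)), g)  # 1 Hz FWHM
  y0 <- ref$intensity
  expect_equal(apply_line_broadening(y0, 0, g), y0)
  y1 <- apply_line_broadening(y0, 0.7, g, 400)
  i0 <- spectrum_integral(y0, g)
  expect_lt(abs(spectrum_integral(y1, g) - i0) / i0, 1e-3)
  # peak height non-increasing in lb
  y2 <- apply_line_broadening(y0, 1.0, g, 400)
  expect_lte(max(y1), max(y0))
  expect_lte(max(y2), max(y1))

  # Lorentzian convolution adds widths: FWHM w + lb
  fwhm_hz <- function(y) {
    x_hz <- ppm_points(g) * 400
    half <- max(y) / 2
    above <- which(y >= half)
    x_hz[max(above)] - x_hz[min(above)]
  }
  expect_equal(fwhm_hz(y2), 2.0, tolerance = 0.05)
  expect_error(apply_line_broadening(y0, -1, g), "non-negative")
})

test_that("chemical-shift jitter is an integer-point translation", {
  g <- ppm_grid(-0.32, 10.21, 46000)
  ref <- synth_reference("s", list(multiplet(3, 2, "doublet", J = 7)), g)
  expect_equal(shift_analyte(ref, 0)$intensity, ref$intensity)
  # 3.4 ppb on the standard grid is a 15-point translation
  sh <- shift_analyte(ref, 3.4)
  k <- round(3.4 / (g$spacing * 1000))
  expect_identical(k, 15)
  expect_equal(sh$intensity[(k + 1):g$n_points],
               ref$intensity[1:(g$n_points - k)])
  # shifting +delta then -delta is the identity away from the edges
  back <- shift_analyte(sh, -3.4)
  mid <- 100:(g$n_points - 100)
  expect_equal(back$intensity[mid], ref$intensity[mid])
  expect_error(shift_analyte(ref, 4.0), "exceeds")
})

test_that("added noise has the requested standard deviation", {
  g <- ppm_grid(-0.32, 10.21, 46000)
  z <- numeric(g$n_points)
  expect_equal(add_noise(z, 0), z)
  set.seed(21)
  s <- 0.037
  y <- add_noise(z, s)
  n <- length(y)
  se_sd <- s / sqrt(2 * (n - 1))
  expect_lt(abs(sd(y) - s), 3 * se_sd)
})

test_that("baseline offsets shift the whole spectrum by a constant", {
  y <- rnorm(500)
  expect_equal(add_baseline(y, 0), y)
  up <- add_baseline(y, 0.25)
  expect_equal(min(up), min(y) + 0.25)
  expect_equal(max(up), max(y) + 0.25)
})

test_that("interference singlets carry the drawn concentration as area", {
  g <- tiny_grid(20000)
  y <- numeric(g$n_points)
  none <- add_interference(y, g, n = 0)
  expect_equal(none$intensity, y)
  expect_identical(nrow(none$record), 0L)
  # forced singlet at a known position and concentration: added area is
  # concentration x unit singlet area (one proton integrates to 1)
  one <- add_interference(y, g, n = 1, positions = 5.0, concentrations = 1.7)
  expect_equal(spectrum_integral(one$intensity, g), 1.7, tolerance = 0.01)
  set.seed(22)
  counts <- vapply(1:200, function(i) {
    nrow(add_interference(y, g)$record)
  }, numeric(1))
  expect_lte(max(counts), 3)
  expect_gte(min(counts), 0)
})

test_that("SNR is peak height over noise SD and is scale invariant", {
  g <- ppm_grid(-0.32, 10.21, 46000)
  ref <- synth_reference("s", list(multiplet(5, 1)), g)
  y0 <- ref$intensity / max(ref$intensity)  # unit peak
  set.seed(23)
  snrs <- vapply(1:20, function(i) {
    compute_snr(add_noise(y0, 0.01), g)
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 100) / 100, 0.10)
  set.seed(24)
  y <- add_noise(y0, 0.01)
  expect_equal(compute_snr(3.7 * y, g), compute_snr(y, g))
  clean <- compute_snr(y0 * 0 + 1e-9, g)
  expect_true(is.infinite(clean))
  expect_true(isTRUE(attr(clean, "infinite")))
})

test_that("noise multiplier follows the 3/2-power field scaling", {
  expect_equal(field_noise_multiplier(400), 1.0)
  expect_equal(field_noise_multiplier(100), 8.0)
  expect_equal(field_noise_multiplier(800), 0.5^1.5)
  expect_equal(1 / field_noise_multiplier(800), 2.828427, tolerance = 1e-6)
  expect_error(field_noise_multiplier(0), "positive")
})

test_that("log compression is exact, monotone, and guarded", {
  expect_identical(log_transform(0), 0)
  expect_equal(log_transform(1), log10(1001))
  x <- seq(0, 1, length.out = 50)
  expect_true(all(diff(log_transform(x)) > 0))
  expect_error(log_transform(c(0.5, -0.01)), "index")
})
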