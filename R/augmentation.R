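# Data-augmentation workflow: every generated mixture receives random
# line broadening, per-analyte chemical-shift jitter, interference
# singlets, Gaussian noise, and a baseline offset, each drawn from the
# configured ranges.

#' Augmentation configuration
#'
#' Ranges for the data-augmentation workflow. Defaults follow the standard
#' protocol: Gaussian noise at 30-115% of the reference noise level,
#' exponential apodization of 0-1 Hz, per-analyte chemical-shift jitter of
#' up to 3.4 ppb in either direction, baseline offsets up to ~5.6% of the
#' internal-standard (TSP) peak height, and up to three interference
#' singlets scaled by the interference concentration distribution.
#'
#' @param noise_fraction_range Noise sigma as a fraction of
#'   `reference_noise_sigma`, drawn uniformly per spectrum.
#' @param lb_range Exponential line-broadening range in Hz.
#' @param shift_range_ppb Maximum per-analyte chemical-shift jitter (ppb).
#' @param baseline_frac Maximum baseline offset as a fraction of the TSP
#'   peak height.
#' @param max_interference Maximum number of interference singlets.
#' @param reference_noise_sigma Reference noise level in intensity units;
#'   `NULL` means "derive from the library" via [default_noise_sigma()].
#' @param enabled Master switch; `FALSE` disables all augmentation (used
#'   by the linearity oracle).
#' @return An `aug_config` list.
#' @export
augmentation_config <- function(noise_fraction_range = c(0.30, 1.15),
                                lb_range = c(0, 1),
                                shift_range_ppb = 3.4,
                                baseline_frac = 0.056,
                                max_interference = 3L,
                                reference_noise_sigma = NULL,
                                enabled = TRUE) {
  stopifnot(all(noise_fraction_range >= 0), all(lb_range >= 0),
            shift_range_ppb >= 0, baseline_frac >= 0, max_interference >= 0)
  structure(
    list(noise_fraction_range = noise_fraction_range, lb_range = lb_range,
         shift_range_ppb = shift_range_ppb, baseline_frac = baseline_frac,
         max_interference = as.integer(max_interference),
         reference_noise_sigma = reference_noise_sigma, enabled = enabled),
    class = "aug_config"
  )
}

#' Default reference noise level for a library
#'
#' The noise level is anchored so that a 1 mM nine-proton singlet (the TSP
#' reference at unit concentration) has a signal-to-noise ratio of
#' `target_snr` at the library's field strength; 300 is representative of
#' a modern 400-MHz instrument. Field-strength scaling is applied on top
#' via [field_noise_multiplier()].
#'
#' @param library A `metabolite_library` (supplies the grid).
#' @param target_snr Target SNR of the 1 mM nine-proton singlet.
#' @param reference_field Field at which the anchor is defined (MHz); the
#'   actual library field is accounted for separately by
#'   [field_noise_multiplier()].
#' @return Scalar noise standard deviation in intensity units.
#' @export
default_noise_sigma <- function(library, target_snr = 300,
                                reference_field = 400) {
  stopifnot(inherits(library, "metabolite_library"))
  anchor <- suppressWarnings(synth_reference(
    "tsp9", list(multiplet(0, 9L)), library$grid, reference_field
  ))
  max(anchor$intensity) / target_snr
}

#' Exponential line broadening of a spectrum
#'
#' Implements apodization through the time domain: the spectrum is
#' inverse-Fourier transformed to a synthetic free-induction decay,
#' multiplied by `exp(-pi * lb * |t|)` (symmetric in time so the real
#' absorption spectrum stays real), and transformed back. This convolves
#' every line with a Lorentzian of width `lb` Hz, so Lorentzian widths add
#' and the total integral is preserved.
#'
#' @param intensity Numeric spectrum vector on `grid`.
#' @param lb Line broadening in Hz (>= 0).
#' @param grid The [ppm_grid()] the spectrum lives on.
#' @param field_strength Spectrometer frequency (MHz), to convert the grid
#'   span to a spectral width in Hz.
#' @return Broadened spectrum vector of the same length.
#' @export
apply_line_broadening <- function(intensity, lb, grid, field_strength = 400) {
  if (lb < 0) abort("`lb` must be non-negative.")
  if (lb == 0) return(intensity)
  n <- length(intensity)
  stopifnot(n == grid$n_points)
  sweep_hz <- (grid$max_ppm - grid$min_ppm) * field_strength
  m <- next_fast_len(n)
  t_sym <- lb_time_axis(m, sweep_hz / n)
  fid <- fft(c(intensity, numeric(m - n)), inverse = TRUE)
  Re(fft(fid * exp(-pi * lb * t_sym)))[seq_len(n)] / m
}

# Smallest 2-3-5-smooth length >= n; mixed-radix FFTs are fast there and
# the zero padding turns the circular convolution into a linear one.
next_fast_len <- function(n) {
  repeat {
    m <- n
    for (f in c(2, 3, 5)) while (m %% f == 0) m <- m / f
    if (m == 1) return(n)
    n <- n + 1
  }
}

# Symmetric time axis for an m-point transform at df Hz per point, so the
# real absorption spectrum stays real under the decay envelope.
lb_time_axis <- function(m, df) {
  k <- 0:(m - 1)
  pmin(k, m - k) / (df * m)
}

# Translate a spectrum by an integer number of grid points, zero-filling
# the vacated edge.
shift_points <- function(intensity, k) {
  n <- length(intensity)
  k <- as.integer(k)
  if (k == 0) return(intensity)
  out <- numeric(n)
  if (k > 0) out[(k + 1):n] <- intensity[1:(n - k)]
  else out[1:(n + k)] <- intensity[(1 - k):n]
  out
}

#' Chemical-shift jitter of a reference spectrum
#'
#' Translates a whole reference along the ppm axis by the nearest integer
#' number of grid points (sub-point interpolation is deliberately avoided
#' so lineshapes are not distorted; on the standard 46,000-point grid one
#' point is ~0.229 ppb). Vacated points are zero-filled.
#'
#' @param reference A `ref_spectrum` or numeric intensity vector.
#' @param delta_ppb Shift in ppb (positive = towards higher ppm).
#' @param grid Required when `reference` is a bare vector.
#' @param max_ppb Configured jitter bound; larger requests are rejected.
#' @return Same type as `reference`, shifted.
#' @export
shift_analyte <- function(reference, delta_ppb, grid = NULL, max_ppb = 3.4) {
  if (abs(delta_ppb) > max_ppb + 1e-12) {
    abort(sprintf("|delta| = %.3g ppb exceeds the configured maximum %.3g ppb.",
                  abs(delta_ppb), max_ppb))
  }
  if (inherits(reference, "ref_spectrum")) {
    grid <- reference$grid
    k <- round(delta_ppb / (grid$spacing * 1000))
    out <- reference
    out$intensity <- shift_points(reference$intensity, k)
    return(out)
  }
  stopifnot(inherits(grid, "ppm_grid"))
  k <- round(delta_ppb / (grid$spacing * 1000))
  shift_points(reference, k)
}

#' Add Gaussian noise to a spectrum
#'
#' @param intensity Spectrum vector.
#' @param sigma Noise standard deviation (>= 0), in intensity units.
#' @return `intensity` plus i.i.d. zero-mean Gaussian noise.
#' @export
add_noise <- function(intensity, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(intensity)
  intensity + rnorm(length(intensity), 0, sigma)
}

#' Add a constant baseline offset
#'
#' @param intensity Spectrum vector.
#' @param offset Constant added pointwise (either sign).
#' @return Shifted spectrum.
#' @export
add_baseline <- function(intensity, offset) {
  intensity + offset
}

#' Add random interference singlets
#'
#' Adds `k` generic one-proton Lorentzian singlets at uniform random
#' chemical shifts, `k` drawn uniformly from `0:max_singlets`, each scaled
#' by a concentration from [sample_interference()].
#'
#' @param intensity Spectrum vector on `grid`.
#' @param grid The [ppm_grid()].
#' @param field_strength Spectrometer frequency (MHz).
#' @param max_singlets Maximum number of singlets (default 3).
#' @param linewidth Singlet FWHM in Hz.
#' @param n Force a specific count (bypasses the uniform draw).
#' @param positions,concentrations Optional forced positions (ppm) and
#'   concentrations (mM) of length `n`.
#' @return List with `intensity` (augmented spectrum) and `record`
#'   (tibble of ppm, mM per added singlet).
#' @export
add_interference <- function(intensity, grid, field_strength = 400,
                             max_singlets = 3L, linewidth = 1.0,
                             n = NULL, positions = NULL,
                             concentrations = NULL) {
  if (is.null(n)) n <- sample(0:max_singlets, 1)
  n <- as.integer(n)
  if (n == 0) {
    return(list(intensity = intensity,
                record = tibble::tibble(ppm = numeric(0), mM = numeric(0))))
  }
  if (is.null(positions)) positions <- runif(n, grid$min_ppm, grid$max_ppm)
  if (is.null(concentrations)) concentrations <- sample_interference(n)
  x <- ppm_points(grid)
  fwhm <- linewidth / field_strength
  for (i in seq_len(n)) {
    intensity <- intensity +
      concentrations[i] * lorentzian(x, positions[i], fwhm)
  }
  list(intensity = intensity,
       record = tibble::tibble(ppm = positions, mM = concentrations))
}

#' Signal-to-noise ratio of a spectrum
#'
#' SNR is the height of the tallest peak divided by the standard deviation
#' of the intensity inside a signal-free noise window (the window is
#' median-centred first, so a baseline offset does not inflate the noise
#' estimate or the peak height reference).
#'
#' @param intensity Spectrum vector on `grid`.
#' @param grid The [ppm_grid()].
#' @param noise_region Length-2 ppm window containing no analyte signal;
#'   the default high-ppm window suits the synthetic library.
#' @return SNR as a scalar; `Inf` with attribute `infinite = TRUE` when the
#'   noise window is exactly constant.
#' @export
compute_snr <- function(intensity, grid, noise_region = c(9.6, 10.2)) {
  stopifnot(length(intensity) == grid$n_points, length(noise_region) == 2)
  x <- ppm_points(grid)
  win <- intensity[x >= noise_region[1] & x <= noise_region[2]]
  if (length(win) < 2) abort("noise region contains fewer than 2 points.")
  sigma <- sd(win - median(win))
  peak <- max(intensity) - median(win)
  if (sigma == 0) {
    return(structure(Inf, infinite = TRUE))
  }
  peak / sigma
}

#' Field-strength noise multiplier
#'
#' SNR scales with the 3/2 power of the field strength, so noise relative
#' to the 400-MHz reference scales by `(reference_field / field)^(3/2)`:
#' 8-fold at 100 MHz and 1/2.8-fold at 800 MHz.
#'
#' @param field Spectrometer frequency in MHz (> 0).
#' @param reference_field Reference frequency (default 400 MHz).
#' @return Multiplier applied to the reference noise sigma.
#' @export
field_noise_multiplier <- function(field, reference_field = 400) {
  if (any(field <= 0)) abort("`field` must be positive.")
  (reference_field / field)^(3 / 2)
}

#' Log-compress spectral intensities
#'
#' `L = log10(1 + 1000 * S)` pointwise, shrinking the dynamic range
#' between the tallest and smallest peaks. Normalised spectra are
#' non-negative up to noise; values at or below `-1/1000` would make the
#' logarithm's argument non-positive and are rejected.
#'
#' @param intensity Spectrum vector (or matrix of spectra).
#' @return Transformed values, same shape.
#' @export
log_transform <- function(intensity) {
  arg <- 1 + 1000 * intensity
  bad <- which(arg <= 0)
  if (length(bad) > 0) {
    abort(sprintf("log argument <= 0 at index/indices: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  log10(arg)
}
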