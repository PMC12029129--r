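#' Split spectra into contiguous bins for sequence models
#'
#' The transformer consumes each spectrum as a sequence of contiguous,
#' non-overlapping bins in ppm order: a 46,000-point spectrum with bin
#' size 1000 becomes a sequence of 46 positions with 1000 features each.
#' When the spectrum length is not a multiple of `bin_size`, the high-ppm
#' end is zero-padded and the padding is recorded.
#'
#' @param spectra A length-N vector or `B x N` matrix of spectra.
#' @param bin_size Points per sequence position (>= 1, <= N).
#' @return Matrix of dimension `(B * n_bins) x bin_size`; row
#'   `(b - 1) * n_bins + s` holds bin `s` of spectrum `b`. Attributes
#'   `n_bins`, `bin_size`, `n_spectra` and `padding` (points added).
#' @examples
#' x <- matrix(rnorm(2 * 400), 2, 400)
#' b <- bin_spectrum(x, 100)
#' attr(b, "n_bins")  # 4
#' @export
bin_spectrum <- function(spectra, bin_size) {
  if (is.null(dim(spectra))) spectra <- matrix(spectra, nrow = 1)
  n <- ncol(spectra)
  bin_size <- as.integer(bin_size)
  if (bin_size < 1L) abort("`bin_size` must be >= 1.")
  if (bin_size > n) abort("`bin_size` exceeds the spectrum length.")
  n_bins <- as.integer(ceiling(n / bin_size))
  pad <- as.integer(n_bins * bin_size - n)
  if (pad > 0) spectra <- cbind(spectra, matrix(0, nrow(spectra), pad))
  B <- nrow(spectra)
  # t(spectra) is (n_bins*bin_size) x B column-major, so reshaping to
  # bin_size x (n_bins*B) puts bin s of spectrum b in column (b-1)*n_bins+s.
  out <- t(matrix(t(spectra), nrow = bin_size))
  structure(out, n_bins = n_bins, bin_size = bin_size, n_spectra = B,
            padding = pad)
}

#' Reassemble binned spectra
#'
#' Inverse of [bin_spectrum()] (padding removed).
#'
#' @param binned Output of [bin_spectrum()].
#' @param n_points Original spectrum length (defaults to the full padded
#'   length).
#' @return `B x n_points` matrix.
#' @export
unbin_spectrum <- function(binned, n_points = NULL) {
  n_bins <- attr(binned, "n_bins")
  B <- attr(binned, "n_spectra")
  full <- t(matrix(t(binned), ncol = B))
  if (!is.null(n_points)) full <- full[, seq_len(n_points), drop = FALSE]
  full
}
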