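#' Construct a uniform chemical-shift grid
#'
#' All spectra in a library share one uniform ppm axis. The conventional
#' acquisition window used throughout the package runs from -0.32 to
#' 10.21 ppm with 46,000 points; index 1 corresponds to `min_ppm` and the
#' axis ascends.
#'
#' @param min_ppm Lower chemical-shift bound (ppm).
#' @param max_ppm Upper chemical-shift bound (ppm); must exceed `min_ppm`.
#' @param n_points Number of grid points (>= 2).
#'
#' @return A `ppm_grid` object with fields `min_ppm`, `max_ppm`, `n_points`
#'   and the derived `spacing` (ppm per point).
#' @examples
#' g <- ppm_grid(-0.32, 10.21, 46000)
#' g$spacing * 1000  # grid resolution in ppb
#' @export
ppm_grid <- function(min_ppm = -0.32, max_ppm = 10.21, n_points = 46000L) {
  stopifnot(is.numeric(min_ppm), is.numeric(max_ppm), is.numeric(n_points))
  if (!(min_ppm < max_ppm)) {
    rlang::abort("`min_ppm` must be strictly less than `max_ppm`.")
  }
  n_points <- as.integer(n_points)
  if (n_points < 2L) {
    rlang::abort("`n_points` must be at least 2.")
  }
  structure(
    list(
      min_ppm = as.numeric(min_ppm),
      max_ppm = as.numeric(max_ppm),
      n_points = n_points,
      spacing = (max_ppm - min_ppm) / (n_points - 1)
    ),
    class = "ppm_grid"
  )
}

#' Chemical-shift axis of a grid
#'
#' @param grid A [ppm_grid()].
#' @return Numeric vector of length `grid$n_points`, strictly increasing,
#'   with first element `min_ppm` and last element `max_ppm` exactly.
#' @export
ppm_points <- function(grid) {
  stopifnot(inherits(grid, "ppm_grid"))
  seq(grid$min_ppm, grid$max_ppm, length.out = grid$n_points)
}

#' Nearest grid index for a chemical shift
#'
#' @param grid A [ppm_grid()].
#' @param ppm Chemical shifts (ppm).
#' @return Integer indices clamped to `[1, n_points]`.
#' @export
ppm_index <- function(grid, ppm) {
  stopifnot(inherits(grid, "ppm_grid"))
  idx <- round((ppm - grid$min_ppm) / grid$spacing) + 1
  pmin(pmax(as.integer(idx), 1L), grid$n_points)
}

#' @export
print.ppm_grid <- function(x, ...) {
  cat(sprintf(
    "<ppm_grid> %g to %g ppm, %d points (%.4g ppb/pt)\n",
    x$min_ppm, x$max_ppm, x$n_points, x$spacing * 1000
  ))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  inherits(a, "ppm_grid") && inherits(b, "ppm_grid") &&
    a$n_points == b$n_points &&
    abs(a$min_ppm - b$min_ppm) < tol &&
    abs(a$max_ppm - b$max_ppm) < tol
}
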