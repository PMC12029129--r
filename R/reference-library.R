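#' @keywords internal
"_PACKAGE"

#' @useDynLib nmrquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom stats approx rnorm runif rgamma rbinom median qt sd fft mvfft
#'   predict quantile setNames lm coef
#' @importFrom utils head tail
NULL

# Evaluate code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Describe one multiplet of a metabolite
#'
#' A multiplet is a group of lines arising from one chemical environment,
#' split by scalar (J) coupling. First-order patterns carry binomial
#' relative intensities; an arbitrary pattern may be given as a numeric
#' vector of relative line intensities (normalised internally to sum to 1).
#'
#' @param center Chemical shift of the multiplet centre (ppm).
#' @param n_protons Number of equivalent protons (>= 1); the multiplet's
#'   integrated area is proportional to this count.
#' @param pattern `"singlet"`, `"doublet"`, `"triplet"`, `"quartet"`, or a
#'   numeric vector of relative line intensities.
#' @param J Coupling constant in Hz (line spacing; ignored for singlets).
#' @param linewidth Lorentzian full width at half maximum in Hz.
#' @return A `multiplet` object.
#' @examples
#' multiplet(1.33, n_protons = 3, pattern = "doublet", J = 7)
#' @export
multiplet <- function(center, n_protons = 1L, pattern = "singlet",
                      J = 7, linewidth = 1.0) {
  n_protons <- as.integer(n_protons)
  if (is.na(n_protons) || n_protons < 1L) {
    abort("`n_protons` must be a positive integer.")
  }
  if (J < 0) abort("`J` must be non-negative.")
  if (linewidth <= 0) abort("`linewidth` must be positive.")
  if (is.character(pattern)) {
    pattern <- match.arg(pattern, c("singlet", "doublet", "triplet", "quartet"))
    n_lines <- match(pattern, c("singlet", "doublet", "triplet", "quartet"))
    rel <- choose(n_lines - 1, 0:(n_lines - 1))
  } else {
    rel <- as.numeric(pattern)
    if (length(rel) < 1 || any(rel < 0) || sum(rel) <= 0) {
      abort("numeric `pattern` must be non-negative relative intensities.")
    }
  }
  rel <- rel / sum(rel)
  structure(
    list(center = as.numeric(center), n_protons = n_protons,
         rel_intensity = rel, J = as.numeric(J),
         linewidth = as.numeric(linewidth)),
    class = "multiplet"
  )
}

# Line positions (ppm) and areas for one multiplet at a given field.
# Areas are n_protons * rel_intensity so that one proton integrates to 1
# across the whole library (the shared proportionality constant).
multiplet_lines <- function(mp, field_strength) {
  m <- length(mp$rel_intensity)
  offsets_hz <- (seq_len(m) - (m + 1) / 2) * mp$J
  tibble::tibble(
    ppm = mp$center + offsets_hz / field_strength,
    area = mp$n_protons * mp$rel_intensity,
    fwhm_ppm = mp$linewidth / field_strength
  )
}

# Absorption-mode Lorentzian with unit area on the ppm axis.
lorentzian <- function(x, x0, fwhm) {
  hw <- fwhm / 2
  (hw / pi) / ((x - x0)^2 + hw^2)
}

#' Synthesise a 1 mM metabolite reference spectrum
#'
#' Renders a list of multiplets as a sum of absorption-mode Lorentzian
#' lines on the shared grid. Line positions are converted from Hz to ppm
#' with the spectrometer frequency, so multiplet footprints in ppm shrink
#' as the field strength grows. Each multiplet integrates to
#' `n_protons` area units: a single proportionality constant shared by the
#' whole library, so integrals encode stoichiometry at 1 mM.
#'
#' @param name Metabolite identifier.
#' @param multiplets List of [multiplet()] objects (possibly empty).
#' @param grid A [ppm_grid()].
#' @param field_strength Spectrometer frequency in MHz (> 0).
#' @return A `ref_spectrum` object: `name`, `grid`, `intensity`
#'   (length `n_points`), `unit_concentration = 1` (mM).
#' @export
synth_reference <- function(name, multiplets, grid, field_strength = 400) {
  stopifnot(inherits(grid, "ppm_grid"))
  if (field_strength <= 0) abort("`field_strength` must be positive.")
  if (inherits(multiplets, "multiplet")) multiplets <- list(multiplets)
  x <- ppm_points(grid)
  intensity <- numeric(grid$n_points)
  if (length(multiplets) == 0) {
    warn(sprintf("empty multiplet list for '%s': zero reference spectrum", name))
  }
  for (mp in multiplets) {
    stopifnot(inherits(mp, "multiplet"))
    lines <- multiplet_lines(mp, field_strength)
    outside <- lines$ppm < grid$min_ppm | lines$ppm > grid$max_ppm
    if (any(outside)) {
      warn(sprintf(
        "'%s': %d line(s) fall outside the grid and are truncated",
        name, sum(outside)
      ))
    }
    for (i in seq_len(nrow(lines))) {
      intensity <- intensity +
        lines$area[i] * lorentzian(x, lines$ppm[i], lines$fwhm_ppm[i])
    }
  }
  new_ref_spectrum(name, grid, intensity)
}

new_ref_spectrum <- function(name, grid, intensity) {
  stopifnot(length(intensity) == grid$n_points, all(is.finite(intensity)))
  structure(
    list(name = name, grid = grid, intensity = as.numeric(intensity),
         unit_concentration = 1),
    class = "ref_spectrum"
  )
}

#' @export
print.ref_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ref_spectrum> %s: %d points, integral %.3f, max %.3g\n",
    x$name, x$grid$n_points, spectrum_integral(x), max(x$intensity)
  ))
  invisible(x)
}

#' Integral of a reference spectrum over the ppm axis
#'
#' Trapezoidal integral; for a truncation-free synthetic reference this is
#' proportional to the total proton count.
#'
#' @param ref A `ref_spectrum` (or a bare intensity vector with `grid`).
#' @param grid Needed only when `ref` is a numeric vector.
#' @return Scalar integral in intensity x ppm units.
#' @export
spectrum_integral <- function(ref, grid = NULL) {
  if (inherits(ref, "ref_spectrum")) {
    y <- ref$intensity
    grid <- ref$grid
  } else {
    y <- as.numeric(ref)
    stopifnot(inherits(grid, "ppm_grid"))
  }
  pracma::trapz(ppm_points(grid), y)
}

#' Combine glucose anomer references into one spectrum
#'
#' In aqueous solution D-glucose equilibrates at roughly 36% alpha and 64%
#' beta anomer, so the two simulated anomer spectra are combined with those
#' weights into a single glucose reference.
#'
#' @param alpha,beta `ref_spectrum` objects on the same grid.
#' @param w_alpha Weight on the alpha anomer in `[0, 1]`; beta receives
#'   `1 - w_alpha`. Default 0.36.
#' @param name Name for the combined spectrum.
#' @return A `ref_spectrum`: `w_alpha * alpha + (1 - w_alpha) * beta`.
#' @export
combine_anomers <- function(alpha, beta, w_alpha = 0.36, name = "glucose") {
  stopifnot(inherits(alpha, "ref_spectrum"), inherits(beta, "ref_spectrum"))
  if (!same_grid(alpha$grid, beta$grid)) {
    abort("anomer references must share the same grid.")
  }
  if (w_alpha < 0 || w_alpha > 1) abort("`w_alpha` must lie in [0, 1].")
  new_ref_spectrum(
    name, alpha$grid,
    w_alpha * alpha$intensity + (1 - w_alpha) * beta$intensity
  )
}

#' Read a reference spectrum from delimited text
#'
#' Expects a header and two numeric columns, `ppm` and `intensity`, with a
#' monotone ppm column. The spectrum is resampled onto the target grid by
#' linear interpolation; grid points outside the file's ppm range are set
#' to zero.
#'
#' @param path File path (comma- or tab-delimited, header required).
#' @param grid Target [ppm_grid()].
#' @param name Metabolite name; defaults to the file stem.
#' @return A `ref_spectrum` on `grid`.
#' @export
read_reference <- function(path, grid, name = NULL) {
  stopifnot(inherits(grid, "ppm_grid"))
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", comment.char = "")
  if (ncol(raw) < 2) abort(sprintf("'%s': need ppm and intensity columns", path))
  ppm <- suppressWarnings(as.numeric(raw[[1]]))
  intensity <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(ppm) | is.na(intensity))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric row(s) in '%s' at line(s): %s",
                  path, paste(bad + 1, collapse = ", ")))
  }
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) {
    abort(sprintf("ppm column in '%s' is not monotone", path))
  }
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  y <- approx(ppm, intensity, xout = ppm_points(grid), rule = 1)$y
  y[is.na(y)] <- 0
  new_ref_spectrum(name, grid, y)
}

#' Write a reference spectrum as delimited text
#'
#' @param ref A `ref_spectrum`.
#' @param path Output path; written as CSV with header `ppm,intensity`.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "ref_spectrum"))
  utils::write.csv(
    data.frame(ppm = ppm_points(ref$grid), intensity = ref$intensity),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Assemble a metabolite library
#'
#' @param references List of `ref_spectrum` objects sharing one grid; names
#'   must be unique. Order is fixed and defines the model output order.
#' @param field_strength Spectrometer frequency in MHz.
#' @param tsp_name Name of the internal-standard entry (not an analyte);
#'   `NULL` when the library carries no internal standard.
#' @return A `metabolite_library`.
#' @export
metabolite_library <- function(references, field_strength = 400,
                               tsp_name = NULL) {
  stopifnot(length(references) >= 1)
  nms <- vapply(references, function(r) r$name, character(1))
  if (anyDuplicated(nms)) abort("reference names must be unique.")
  grid <- references[[1]]$grid
  for (r in references) {
    if (!same_grid(r$grid, grid)) abort("all references must share one grid.")
  }
  names(references) <- nms
  if (!is.null(tsp_name) && !tsp_name %in% nms) {
    abort(sprintf("tsp_name '%s' not found among references.", tsp_name))
  }
  structure(
    list(grid = grid, references = references,
         field_strength = field_strength, tsp_name = tsp_name,
         analytes = setdiff(nms, tsp_name)),
    class = "metabolite_library"
  )
}

#' @export
print.metabolite_library <- function(x, ...) {
  cat(sprintf(
    "<metabolite_library> %d analytes%s at %g MHz on [%g, %g] ppm (%d pts)\n",
    length(x$analytes),
    if (is.null(x$tsp_name)) "" else sprintf(" + %s", x$tsp_name),
    x$field_strength, x$grid$min_ppm, x$grid$max_ppm, x$grid$n_points
  ))
  invisible(x)
}

#' Reference spectra as a matrix
#'
#' @param library A `metabolite_library`.
#' @param analytes_only Drop the internal-standard column?
#' @return Matrix `n_points x n_references`, columns named and ordered as
#'   the library.
#' @export
ref_matrix <- function(library, analytes_only = FALSE) {
  stopifnot(inherits(library, "metabolite_library"))
  nms <- if (analytes_only) library$analytes else names(library$references)
  vapply(library$references[nms], function(r) r$intensity,
         numeric(library$grid$n_points))
}

#' Load a metabolite library from a manifest file
#'
#' The manifest is one YAML file with fields `grid` (`min_ppm`,
#' `max_ppm`, `n_points`), `field_strength`, optionally `tsp` (the name
#' of the internal-standard entry), and `references`: a mapping from
#' metabolite name to a delimited-text spectrum file (path relative to
#' the manifest). Every file is resampled onto the manifest grid.
#'
#' @param path Manifest path.
#' @return A `metabolite_library`.
#' @export
read_library_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  for (f in c("grid", "field_strength", "references")) {
    if (is.null(man[[f]])) abort(sprintf("manifest is missing '%s'", f))
  }
  grid <- ppm_grid(man$grid$min_ppm, man$grid$max_ppm, man$grid$n_points)
  base <- dirname(path)
  refs <- lapply(names(man$references), function(nm) {
    fp <- man$references[[nm]]
    if (!file.exists(fp)) fp <- file.path(base, fp)
    read_reference(fp, grid, name = nm)
  })
  metabolite_library(refs, field_strength = man$field_strength,
                     tsp_name = man$tsp)
}

#' Write a library manifest and its reference files
#'
#' Inverse of [read_library_manifest()]: one CSV per reference plus
#' `manifest.yaml` in `dir`.
#'
#' @param library A `metabolite_library`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_library_manifest <- function(library, dir) {
  stopifnot(inherits(library, "metabolite_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- setNames(paste0(names(library$references), ".csv"),
                    names(library$references))
  for (nm in names(files)) {
    write_reference(library$references[[nm]], file.path(dir, files[nm]))
  }
  man <- list(
    grid = list(min_ppm = library$grid$min_ppm,
                max_ppm = library$grid$max_ppm,
                n_points = library$grid$n_points),
    field_strength = library$field_strength,
    tsp = library$tsp_name,
    references = as.list(files)
  )
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(file.path(dir, "manifest.yaml"))
}

#' Generate a synthetic metabolite library
#'
#' Stand-in for database-downloaded spin-simulated references: each
#' metabolite receives 1-4 first-order multiplets with proton-count
#' proportional areas. Centres are drawn with realistic crowding (the
#' majority in the 1-4.5 ppm aliphatic region), at least one deliberately
#' overlapping metabolite pair is included for `n_metabolites >= 8`, and a
#' 9-proton internal-standard singlet at 0.0 ppm (TSP) is appended as a
#' non-analyte entry. Deterministic for a fixed seed.
#'
#' @param n_metabolites Number of analytes (>= 1).
#' @param field_strength Spectrometer frequency in MHz.
#' @param seed Integer seed.
#' @param grid Shared [ppm_grid()]; defaults to the standard
#'   -0.32 to 10.21 ppm, 46,000-point window.
#' @param linewidth Lorentzian FWHM in Hz before broadening.
#' @return A `metabolite_library` with `n_metabolites` analytes plus TSP.
#' @examples
#' lib <- default_library(8, seed = 1, grid = ppm_grid(n_points = 4000))
#' lib
#' @export
default_library <- function(n_metabolites, field_strength = 400, seed = 1,
                            grid = ppm_grid(), linewidth = 1.0) {
  n_metabolites <- as.integer(n_metabolites)
  if (n_metabolites < 1L) abort("`n_metabolites` must be >= 1.")
  patterns <- c("singlet", "doublet", "triplet", "quartet")
  refs <- with_seed(seed, {
    out <- vector("list", n_metabolites)
    first_centers <- rep(NA_real_, n_metabolites)
    for (i in seq_len(n_metabolites)) {
      k <- sample(1:4, 1)
      centers <- ifelse(runif(k) < 0.75, runif(k, 1.0, 4.5), runif(k, 0.5, 9.5))
      if (i == 2L && n_metabolites >= 8L) {
        # force a crowded pair: first multiplet sits 2 Hz from metabolite 1's
        centers[1] <- first_centers[1] + 2 / field_strength
      }
      first_centers[i] <- centers[1]
      mps <- lapply(seq_len(k), function(j) {
        multiplet(
          center = centers[j],
          n_protons = sample(1:6, 1, prob = c(3, 3, 3, 2, 1, 1)),
          pattern = sample(patterns, 1, prob = c(3, 3, 2, 1)),
          J = runif(1, 2, 12),
          linewidth = linewidth
        )
      })
      out[[i]] <- synth_reference(sprintf("met%02d", i), mps, grid,
                                  field_strength)
    }
    out
  })
  tsp <- synth_reference(
    "TSP", list(multiplet(0.0, n_protons = 9L, pattern = "singlet",
                          linewidth = linewidth)),
    grid, field_strength
  )
  metabolite_library(c(refs, list(tsp)), field_strength, tsp_name = "TSP")
}
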