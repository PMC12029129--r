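# Mixture composition and dataset generation. A mixture spectrum is the
# concentration-weighted sum of 1 mM reference spectra plus the fixed
# 0.3 mM TSP internal standard, passed through the augmentation workflow.

#' Compose a mixture spectrum from the library
#'
#' Intensity is `sum_i c_i * reference_i` over the analytes, plus
#' `tsp_mM * TSP_reference` when the internal standard is included. No
#' augmentation is applied here.
#'
#' @param library A `metabolite_library`.
#' @param concentrations Non-negative mM vector over the library's
#'   analytes (0 = analyte left out), optionally named.
#' @param include_tsp Add the internal standard?
#' @param tsp_mM TSP concentration; fixed at 0.3 mM by convention.
#' @return A `mixture_spectrum`: `intensity`, named `concentrations`,
#'   `tsp_mM`, `grid`, and an empty augmentation record.
#' @export
compose_mixture <- function(library, concentrations, include_tsp = TRUE,
                            tsp_mM = 0.3) {
  stopifnot(inherits(library, "metabolite_library"))
  a <- length(library$analytes)
  if (length(concentrations) != a) {
    abort(sprintf("expected %d analyte concentrations, got %d.",
                  a, length(concentrations)))
  }
  if (any(concentrations < 0)) abort("concentrations must be non-negative.")
  refs <- ref_matrix(library, analytes_only = TRUE)
  intensity <- as.numeric(refs %*% concentrations)
  if (include_tsp && !is.null(library$tsp_name)) {
    intensity <- intensity +
      tsp_mM * library$references[[library$tsp_name]]$intensity
  }
  structure(
    list(intensity = intensity,
         concentrations = setNames(as.numeric(concentrations),
                                   library$analytes),
         tsp_mM = if (include_tsp) tsp_mM else 0,
         grid = library$grid,
         augmentation = list(), source_tag = NA_character_),
    class = "mixture_spectrum"
  )
}

#' @export
print.mixture_spectrum <- function(x, ...) {
  cat(sprintf(
    "<mixture_spectrum> %d points, %d/%d analytes present, TSP %.2g mM\n",
    length(x$intensity), sum(x$concentrations > 0),
    length(x$concentrations), x$tsp_mM
  ))
  invisible(x)
}

# Shift all columns of a p x a reference matrix by k grid points.
shift_ref_matrix <- function(R, k) {
  if (k == 0) return(R)
  out <- matrix(0, nrow(R), ncol(R))
  p <- nrow(R)
  if (k > 0) out[(k + 1):p, ] <- R[1:(p - k), , drop = FALSE]
  else out[1:(p + k), ] <- R[(1 - k):p, , drop = FALSE]
  out
}

#' Generate a simulated spectral dataset
#'
#' Runs the full generation pipeline for `n_spectra` mixtures: draw the
#' analyte presence mask, draw concentrations, compose each spectrum from
#' the (per-analyte jittered) references plus the 0.3 mM TSP standard,
#' apply line broadening, interference singlets, noise and baseline
#' offset, then normalise the whole dataset by its maximum intensity and
#' split 80:20 into training and validation. Fully reproducible from
#' `seed`. The ground-truth table records pre-normalisation
#' concentrations in mM.
#'
#' @param library A `metabolite_library`.
#' @param n_spectra Number of spectra to generate.
#' @param sampler A [conc_sampler()] (default uniform 0.005-20 mM).
#' @param scheme Leave-out scheme, see [leave_out_mask()].
#' @param augmentation An [augmentation_config()].
#' @param seed Integer seed.
#' @param split_frac Training fraction of the train/validation split.
#' @param normalize Normalise by the dataset maximum? (Training pipelines
#'   expect normalised input; the linearity oracle may disable it.)
#' @param log_input Apply [log_transform()] to the normalised spectra?
#' @return A `spectral_dataset`: `spectra` (matrix `n_spectra x n_points`),
#'   `truth` (matrix `n_spectra x n_analytes`, mM), `tsp_mM` (vector, all
#'   0.3), `grid`, `analytes`, `field_strength`, `norm_constant`, `split`
#'   (train/validation index vectors), `record` (per-spectrum augmentation
#'   tibble) and `manifest`.
#' @export
build_dataset <- function(library, n_spectra,
                          sampler = conc_sampler("uniform"),
                          scheme = c("all_present", "half50", "tiered"),
                          augmentation = augmentation_config(),
                          seed = 1, split_frac = 0.8, normalize = TRUE,
                          log_input = FALSE) {
  stopifnot(inherits(library, "metabolite_library"),
            inherits(augmentation, "aug_config"))
  scheme <- match.arg(scheme)
  if (any(augmentation$lb_range < 0) ||
      diff(augmentation$noise_fraction_range) < 0) {
    abort("invalid augmentation ranges.")
  }
  grid <- library$grid
  a <- length(library$analytes)
  p <- grid$n_points
  aug_on <- isTRUE(augmentation$enabled)

  base_sigma <- augmentation$reference_noise_sigma
  if (is.null(base_sigma)) base_sigma <- default_noise_sigma(library)
  sigma_ref <- base_sigma * field_noise_multiplier(library$field_strength)

  tsp_mM <- 0.3
  tsp_vec <- if (!is.null(library$tsp_name)) {
    library$references[[library$tsp_name]]$intensity
  } else {
    numeric(p)
  }
  tsp_peak <- tsp_mM * max(tsp_vec)

  out <- with_seed(seed, {
    mask <- leave_out_mask(n_spectra, a, scheme)
    conc <- draw_concentrations(sampler, n_spectra, a)
    source_tag <- attr(conc, "source")
    conc[!mask] <- 0

    # Per-analyte chemical-shift jitter, realised as integer-point moves.
    if (aug_on && augmentation$shift_range_ppb > 0) {
      delta_ppb <- matrix(
        runif(n_spectra * a, -augmentation$shift_range_ppb,
              augmentation$shift_range_ppb),
        n_spectra, a
      )
    } else {
      delta_ppb <- matrix(0, n_spectra, a)
    }
    kmat <- round(delta_ppb / (grid$spacing * 1000))

    refs <- ref_matrix(library, analytes_only = TRUE)
    X <- matrix(0, n_spectra, p)
    for (k in sort(unique(as.vector(kmat)))) {
      Ck <- conc
      Ck[kmat != k] <- 0
      if (all(Ck == 0)) next
      X <- X + Ck %*% t(shift_ref_matrix(refs, k))
    }
    if (tsp_peak > 0) X <- X + rep(1, n_spectra) %*% t(tsp_mM * tsp_vec)

    if (aug_on) {
      lb <- runif(n_spectra, augmentation$lb_range[1], augmentation$lb_range[2])
      noise_frac <- runif(n_spectra, augmentation$noise_fraction_range[1],
                          augmentation$noise_fraction_range[2])
      baseline <- runif(n_spectra, -augmentation$baseline_frac,
                        augmentation$baseline_frac) * tsp_peak
      n_intf <- sample(0:augmentation$max_interference, n_spectra,
                       replace = TRUE)
      intf <- vector("list", n_spectra)

      # line broadening, batched through the time domain in chunks
      sweep_hz <- (grid$max_ppm - grid$min_ppm) * library$field_strength
      m <- next_fast_len(p)
      t_sym <- lb_time_axis(m, sweep_hz / p)
      for (start in seq(1, n_spectra, by = 256L)) {
        idx <- start:min(n_spectra, start + 255L)
        Z <- matrix(0, m, length(idx))
        Z[seq_len(p), ] <- t(X[idx, , drop = FALSE])
        fid <- mvfft(Z, inverse = TRUE)
        env <- exp(-pi * outer(t_sym, lb[idx]))
        X[idx, ] <- t(Re(mvfft(fid * env))[seq_len(p), , drop = FALSE]) / m
      }

      empty_rec <- tibble::tibble(ppm = numeric(0), mM = numeric(0))
      for (i in seq_len(n_spectra)) {
        if (n_intf[i] == 0) {
          intf[[i]] <- empty_rec
          next
        }
        res <- add_interference(X[i, ], grid, library$field_strength,
                                n = n_intf[i], linewidth = 1.0)
        X[i, ] <- res$intensity
        intf[[i]] <- res$record
      }
      X <- X + matrix(rnorm(n_spectra * p), n_spectra, p) *
        (noise_frac * sigma_ref)
      X <- X + baseline
    } else {
      lb <- numeric(n_spectra)
      noise_frac <- numeric(n_spectra)
      baseline <- numeric(n_spectra)
      n_intf <- integer(n_spectra)
      intf <- rep(list(tibble::tibble(ppm = numeric(0), mM = numeric(0))),
                  n_spectra)
    }

    n_train <- round(split_frac * n_spectra)
    train_idx <- sort(sample.int(n_spectra, n_train))
    list(X = X, conc = conc, source_tag = source_tag, delta_ppb = delta_ppb,
         kmat = kmat, lb = lb, noise_frac = noise_frac, baseline = baseline,
         n_intf = n_intf, intf = intf, train_idx = train_idx)
  })

  colnames(out$conc) <- library$analytes
  record <- tibble::tibble(
    spectrum = seq_len(n_spectra),
    source = out$source_tag,
    lb_hz = out$lb,
    noise_fraction = out$noise_frac,
    noise_sigma = out$noise_frac * sigma_ref,
    baseline = out$baseline,
    n_interference = out$n_intf,
    interference = out$intf,
    shift_ppb = lapply(seq_len(n_spectra), function(i) out$delta_ppb[i, ]),
    shift_points = lapply(seq_len(n_spectra), function(i) out$kmat[i, ])
  )

  ds <- structure(
    list(
      spectra = out$X,
      truth = out$conc,
      tsp_mM = rep(tsp_mM, n_spectra),
      grid = grid,
      analytes = library$analytes,
      field_strength = library$field_strength,
      norm_constant = 1,
      split = list(train = out$train_idx,
                   validation = setdiff(seq_len(n_spectra), out$train_idx)),
      record = record,
      manifest = list(
        seed = seed, n_spectra = n_spectra, sampler = sampler$kind,
        extended_range = sampler$extended_range, scheme = scheme,
        augmentation = unclass(augmentation)[
          c("noise_fraction_range", "lb_range", "shift_range_ppb",
            "baseline_frac", "max_interference", "enabled")],
        reference_noise_sigma = sigma_ref,
        split_frac = split_frac, log_input = log_input,
        library = list(n_analytes = a,
                       field_strength = library$field_strength,
                       tsp = library$tsp_name)
      )
    ),
    class = "spectral_dataset"
  )
  if (normalize) ds <- normalize_dataset(ds)
  if (log_input) ds$spectra <- log_transform(ds$spectra)
  ds
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d spectra x %d points, %d analytes (%s, %s)\n",
    nrow(x$spectra), ncol(x$spectra), length(x$analytes),
    x$manifest$sampler, x$manifest$scheme
  ))
  cat(sprintf("  split %d/%d, norm constant %.4g, %g MHz\n",
              length(x$split$train), length(x$split$validation),
              x$norm_constant, x$field_strength))
  invisible(x)
}

#' Normalise a dataset by its maximum intensity
#'
#' Divides every spectrum by one dataset-wide maximum so the global
#' maximum becomes exactly 1. Ground-truth concentrations are unchanged
#' (they remain in mM). By default the dataset's own maximum is used
#' ("per dataset" normalisation); a constant from another dataset (e.g.
#' the training set) may be supplied instead.
#'
#' @param dataset A `spectral_dataset`.
#' @param constant Optional externally supplied normalisation constant.
#' @return The dataset with rescaled `spectra` and updated
#'   `norm_constant` (cumulative if normalised repeatedly).
#' @export
normalize_dataset <- function(dataset, constant = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  m <- if (is.null(constant)) max(dataset$spectra) else constant
  if (!is.finite(m) || m <= 0) {
    abort("cannot normalise: dataset maximum is not positive.")
  }
  dataset$spectra <- dataset$spectra / m
  dataset$norm_constant <- dataset$norm_constant * m
  dataset
}

#' Ground truth as a tibble
#'
#' @param dataset A `spectral_dataset`.
#' @return Tibble with `spectrum`, `split`, `source`, one column per
#'   analyte (mM) and the fixed TSP concentration.
#' @export
truth_table <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  n <- nrow(dataset$truth)
  split <- rep("validation", n)
  split[dataset$split$train] <- "train"
  dplyr::bind_cols(
    tibble::tibble(spectrum = seq_len(n), split = split,
                   source = dataset$record$source),
    tibble::as_tibble(dataset$truth),
    tibble::tibble(TSP = dataset$tsp_mM)
  )
}

#' Quantify spectra by non-negative least squares
#'
#' The classical linear baseline (and the package's independent oracle):
#' regress each spectrum onto the reference library under non-negativity,
#' returning concentration estimates in mM. With augmentation disabled
#' this recovers the simulated concentrations essentially exactly; under
#' augmentation it is the floor the neural networks are expected to beat.
#'
#' @param dataset A `spectral_dataset` (normalisation is undone via its
#'   `norm_constant`), or a bare `n x p` spectra matrix in raw units.
#' @param library The `metabolite_library` used to generate the spectra.
#' @param include_tsp Include the internal-standard column in the design
#'   (its coefficient is discarded)?
#' @param include_intercept Include a constant column to absorb baseline
#'   offsets?
#' @return Matrix `n x n_analytes` of estimated concentrations (mM).
#' @export
nnls_quantify <- function(dataset, library, include_tsp = TRUE,
                          include_intercept = FALSE) {
  stopifnot(inherits(library, "metabolite_library"))
  if (inherits(dataset, "spectral_dataset")) {
    X <- dataset$spectra * dataset$norm_constant
  } else {
    X <- as.matrix(dataset)
  }
  A <- ref_matrix(library, analytes_only = TRUE)
  a <- ncol(A)
  if (include_tsp && !is.null(library$tsp_name)) {
    A <- cbind(A, library$references[[library$tsp_name]]$intensity)
  }
  if (include_intercept) A <- cbind(A, 1)
  est <- matrix(0, nrow(X), a)
  colnames(est) <- library$analytes
  for (i in seq_len(nrow(X))) {
    est[i, ] <- pracma::lsqnonneg(A, X[i, ])$x[seq_len(a)]
  }
  est
}

#' Write a dataset to a directory
#'
#' Serialises the dataset as plain text: `manifest.yaml` (config, seed,
#' grid, split, normalisation constant), `spectra.csv` (intensity matrix)
#' and `truth.csv` (mM, column order = library analyte order).
#'
#' @param dataset A `spectral_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(dataset$manifest, list(
    grid = list(min_ppm = dataset$grid$min_ppm,
                max_ppm = dataset$grid$max_ppm,
                n_points = dataset$grid$n_points),
    norm_constant = dataset$norm_constant,
    analytes = as.list(dataset$analytes),
    split = list(train = dataset$split$train,
                 validation = dataset$split$validation),
    source = as.character(dataset$record$source)
  ))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  data.table::fwrite(data.table::as.data.table(dataset$spectra),
                     file.path(dir, "spectra.csv"))
  data.table::fwrite(data.table::as.data.table(dataset$truth),
                     file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `spectral_dataset` (augmentation record reduced to the
#'   serialised source tags).
#' @export
read_dataset <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  X <- as.matrix(data.table::fread(file.path(dir, "spectra.csv")))
  truth <- as.matrix(data.table::fread(file.path(dir, "truth.csv")))
  dimnames(X) <- NULL
  grid <- ppm_grid(man$grid$min_ppm, man$grid$max_ppm, man$grid$n_points)
  n <- nrow(X)
  structure(
    list(
      spectra = X, truth = truth, tsp_mM = rep(0.3, n), grid = grid,
      analytes = unlist(man$analytes),
      field_strength = man$library$field_strength,
      norm_constant = man$norm_constant,
      split = list(train = unlist(man$split$train),
                   validation = unlist(man$split$validation)),
      record = tibble::tibble(spectrum = seq_len(n),
                              source = factor(unlist(man$source))),
      manifest = man[setdiff(names(man),
                             c("grid", "norm_constant", "analytes", "split",
                               "source"))]
    ),
    class = "spectral_dataset"
  )
}
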