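# Concentration distributions used to scale the 1 mM references when
# composing training mixtures. The working range is 0.005-20 mM; draws are
# clipped into the range (clipping mass is < 2% for all defaults).

clip_conc <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Uniform concentration sampler
#'
#' Covers the full working concentration range uniformly.
#'
#' @param n Number of draws.
#' @param lo,hi Range in mM; defaults 0.005 and 20.
#' @return Numeric vector of `n` concentrations in mM.
#' @export
sample_uniform <- function(n, lo = 0.005, hi = 20) {
  if (lo <= 0 || lo > hi) abort("need 0 < lo <= hi.")
  runif(n, lo, hi)
}

#' Low-concentration sampler
#'
#' Evenly split mixture of three uniforms, each starting at 0.005 mM and
#' extending to 0.05, 0.1 and 0.2 mM respectively.
#'
#' @param n Number of draws.
#' @return Numeric vector of `n` concentrations in mM, all within
#'   `[0.005, 0.2]`.
#' @export
sample_low_concentration <- function(n) {
  if (n == 0) return(numeric(0))
  hi <- sample(c(0.05, 0.1, 0.2), n, replace = TRUE)
  runif(n, 0.005, hi)
}

#' Tissue-mimicking concentration sampler
#'
#' Mixture of two log-normal components emulating tissue-extract profiles:
#' most metabolites sit well below 1 mM while a heavy tail reaches the top
#' of the range. Draws are clipped to `[0.005, 20]` mM.
#'
#' @param n Number of draws.
#' @param params List with `weight` (on component 1), `meanlog` and `sdlog`
#'   (length-2 each). Defaults put >= 70% of mass below 1 mM.
#' @return Numeric vector of `n` concentrations in mM.
#' @export
sample_mimic_tissue <- function(n, params = mimic_tissue_params()) {
  if (any(params$sdlog < 0)) abort("log-sd must be non-negative.")
  if (n == 0) return(numeric(0))
  comp <- 1L + (runif(n) >= params$weight)
  x <- exp(rnorm(n, params$meanlog[comp], params$sdlog[comp]))
  clip_conc(x, 0.005, 20)
}

#' @rdname sample_mimic_tissue
#' @export
mimic_tissue_params <- function() {
  list(weight = 0.75, meanlog = log(c(0.15, 2.5)), sdlog = c(1.0, 0.9))
}

#' High-dynamic-range concentration sampler
#'
#' Mixture of two gamma components and one uniform component, emphasising
#' low concentrations while keeping mass across the full range. Draws are
#' clipped to `[0.005, 20]` mM.
#'
#' @param n Number of draws.
#' @param params List with `weights` (length 3, summing to 1), `shape` and
#'   `scale` (length 2, gamma components), and `unif` (c(lo, hi)).
#' @return Numeric vector of `n` concentrations in mM.
#' @export
sample_high_dynamic <- function(n, params = high_dynamic_params()) {
  if (abs(sum(params$weights) - 1) > 1e-9) {
    abort("mixture weights must sum to 1.")
  }
  if (n == 0) return(numeric(0))
  comp <- sample.int(3L, n, replace = TRUE, prob = params$weights)
  x <- numeric(n)
  for (j in 1:2) {
    idx <- which(comp == j)
    x[idx] <- rgamma(length(idx), shape = params$shape[j],
                     scale = params$scale[j])
  }
  idx <- which(comp == 3L)
  x[idx] <- runif(length(idx), params$unif[1], params$unif[2])
  clip_conc(x, 0.005, 20)
}

#' @rdname sample_high_dynamic
#' @export
high_dynamic_params <- function() {
  list(weights = c(0.4, 0.35, 0.25), shape = c(1.5, 2), scale = c(0.2, 2),
       unif = c(0.005, 20))
}

#' Interference-singlet concentration sampler
#'
#' Gamma distribution with mean 0.85 mM promoting mostly concentrations
#' under 5 mM; used to scale the random interference singlets added during
#' augmentation.
#'
#' @param n Number of draws.
#' @param shape Gamma shape; scale is `0.85 / shape` so the mean stays
#'   0.85 mM.
#' @return Numeric vector of `n` concentrations in mM.
#' @export
sample_interference <- function(n, shape = 1.2) {
  if (n == 0) return(numeric(0))
  clip_conc(rgamma(n, shape = shape, scale = 0.85 / shape), 0.005, 20)
}

#' Per-spectrum combined concentration sampler
#'
#' Each spectrum is assigned one of the four training distributions
#' (uniform, low concentration, mimic tissue, high dynamic range) with
#' probability 1/4, and all analyte concentrations in that spectrum are
#' drawn from the assigned distribution.
#'
#' @param n_spectra,n_analytes Matrix dimensions.
#' @param stratified When `TRUE`, sources are assigned in strict rotation
#'   (exactly `n_spectra/4` per source when divisible) instead of i.i.d.
#' @param lo,hi Range passed to the uniform component.
#' @return Matrix `n_spectra x n_analytes` with attribute `source` (factor
#'   of the per-spectrum distribution).
#' @export
sample_combined <- function(n_spectra, n_analytes, stratified = FALSE,
                            lo = 0.005, hi = 20) {
  sources <- c("uniform", "low_concentration", "mimic_tissue", "high_dynamic")
  src <- if (stratified) {
    rep_len(sources, n_spectra)[sample.int(n_spectra)]
  } else {
    sample(sources, n_spectra, replace = TRUE)
  }
  out <- matrix(0, n_spectra, n_analytes)
  for (s in sources) {
    idx <- which(src == s)
    m <- length(idx) * n_analytes
    draws <- switch(s,
      uniform = sample_uniform(m, lo, hi),
      low_concentration = sample_low_concentration(m),
      mimic_tissue = sample_mimic_tissue(m),
      high_dynamic = sample_high_dynamic(m)
    )
    out[idx, ] <- draws
  }
  attr(out, "source") <- factor(src, levels = sources)
  out
}

#' Concentration sampler specification
#'
#' Bundles a named distribution with its parameters for use by
#' [build_dataset()]. The `"extended"` option raises the upper limit of
#' the uniform range from 20 to 24 mM.
#'
#' @param kind One of `"uniform"`, `"low_concentration"`, `"mimic_tissue"`,
#'   `"high_dynamic"`, `"combined"`.
#' @param extended_range Extend the uniform upper limit to 24 mM?
#' @param ... Parameter overrides passed to the underlying sampler.
#' @return A `conc_sampler` object; call it via [draw_concentrations()].
#' @export
conc_sampler <- function(kind = c("uniform", "low_concentration",
                                  "mimic_tissue", "high_dynamic", "combined"),
                         extended_range = FALSE, ...) {
  kind <- match.arg(kind)
  structure(
    list(kind = kind, extended_range = extended_range,
         hi = if (extended_range) 24 else 20, lo = 0.005, params = list(...)),
    class = "conc_sampler"
  )
}

#' Draw a concentration matrix from a sampler specification
#'
#' @param sampler A [conc_sampler()].
#' @param n_spectra,n_analytes Matrix dimensions.
#' @return Matrix `n_spectra x n_analytes` (mM) with attribute `source`.
#' @export
draw_concentrations <- function(sampler, n_spectra, n_analytes) {
  stopifnot(inherits(sampler, "conc_sampler"))
  m <- n_spectra * n_analytes
  if (sampler$kind == "combined") {
    return(do.call(sample_combined,
                   c(list(n_spectra, n_analytes, lo = sampler$lo,
                          hi = sampler$hi), sampler$params)))
  }
  draws <- switch(sampler$kind,
    uniform = do.call(sample_uniform,
                      c(list(m, lo = sampler$lo, hi = sampler$hi),
                        sampler$params)),
    low_concentration = sample_low_concentration(m),
    mimic_tissue = do.call(sample_mimic_tissue, c(list(m), sampler$params)),
    high_dynamic = do.call(sample_high_dynamic, c(list(m), sampler$params))
  )
  out <- matrix(draws, n_spectra, n_analytes)
  attr(out, "source") <- factor(rep(sampler$kind, n_spectra))
  out
}

#' Analyte presence mask for leave-out schemes
#'
#' Controls which analytes appear in each training spectrum:
#' `all_present` keeps every analyte in every spectrum; `half50` keeps the
#' first half of spectra complete while each analyte in the second half is
#' independently present with probability 0.5; `tiered` splits spectra in
#' thirds with presence probabilities 1, 0.5 and 0.25.
#'
#' @param n_spectra,n_analytes Mask dimensions.
#' @param scheme `"all_present"`, `"half50"`, or `"tiered"`.
#' @return Logical matrix `n_spectra x n_analytes`; `TRUE` = present.
#' @export
leave_out_mask <- function(n_spectra, n_analytes,
                           scheme = c("all_present", "half50", "tiered")) {
  scheme <- match.arg(scheme)
  stopifnot(n_spectra >= 1, n_analytes >= 1)
  mask <- matrix(TRUE, n_spectra, n_analytes)
  if (scheme == "half50") {
    lower <- seq_len(n_spectra) > n_spectra / 2
    mask[lower, ] <- matrix(runif(sum(lower) * n_analytes) < 0.5,
                            sum(lower), n_analytes)
  } else if (scheme == "tiered") {
    tier <- ceiling(3 * seq_len(n_spectra) / n_spectra)
    p <- c(1, 0.5, 0.25)[tier]
    mask[] <- runif(n_spectra * n_analytes) < rep(p, n_analytes)
  }
  mask
}
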