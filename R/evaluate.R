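# MAPE-based model comparison: per-spectrum mean absolute percent error,
# its mean with a 95% confidence interval over test spectra, and
# normalisation against a baseline report for dataset-modification
# studies.

#' Per-spectrum mean absolute percent error
#'
#' For each spectrum, averages `100 * |pred - truth| / truth` over the
#' analytes (`mode = "spectrum"`, the reporting convention used
#' throughout), or pools all analyte errors (`mode = "pooled"`, returning
#' one value). Test sets always include every analyte, so zero truth
#' entries are rejected.
#'
#' @param pred,truth `n x a` matrices in mM; truth strictly positive.
#' @param mode `"spectrum"` or `"pooled"`.
#' @return Numeric vector of per-spectrum MAPE (%) — length `n` — or a
#'   single pooled value.
#' @examples
#' mape_per_spectrum(matrix(c(1.5, 3), 1), matrix(c(1, 4), 1))  # 37.5
#' @export
mape_per_spectrum <- function(pred, truth, mode = c("spectrum", "pooled")) {
  mode <- match.arg(mode)
  pred <- as.matrix(pred)
  truth <- as.matrix(truth)
  stopifnot(identical(dim(pred), dim(truth)))
  if (any(truth <= 0)) {
    abort("MAPE undefined: truth contains non-positive entries.")
  }
  rel <- 100 * abs(pred - truth) / truth
  if (mode == "pooled") return(mean(rel))
  rowMeans(rel)
}

#' Summarise per-spectrum MAPE
#'
#' Mean with a Student-t 95% confidence interval over the test spectra.
#'
#' @param per_spectrum_mape Numeric vector of per-spectrum MAPE (%).
#' @param conf Confidence level.
#' @return Tibble with `mean_mape`, `ci_lo`, `ci_hi`, `n`. With a single
#'   spectrum the interval is `NA` (flagged undefined).
#' @export
mape_summary <- function(per_spectrum_mape, conf = 0.95) {
  x <- as.numeric(per_spectrum_mape)
  n <- length(x)
  m <- mean(x)
  if (n < 2) {
    return(tibble::tibble(mean_mape = m, ci_lo = NA_real_, ci_hi = NA_real_,
                          n = n))
  }
  se <- sd(x) / sqrt(n)
  tq <- qt(1 - (1 - conf) / 2, df = n - 1)
  tibble::tibble(mean_mape = m, ci_lo = m - tq * se, ci_hi = m + tq * se,
                 n = n)
}

#' Evaluate a model on a test dataset
#'
#' Predicts concentrations for every spectrum and reports per-spectrum
#' MAPE with its mean and 95% confidence interval.
#'
#' @param model An `nn_model` or `trained_model`.
#' @param dataset A `spectral_dataset` whose truth is strictly positive
#'   (all-present test sets), or a list with `spectra` and `truth`.
#' @param model_id,test_id Identifiers recorded in the report.
#' @return An `eval_report`: tibble `per_spectrum` (spectrum, mape),
#'   `summary` (mean + CI), ids, and the prediction matrix.
#' @export
evaluate_model <- function(model, dataset, model_id = "model",
                           test_id = "test") {
  pred <- predict(model, dataset$spectra)
  per <- mape_per_spectrum(pred, dataset$truth)
  structure(
    list(
      per_spectrum = tibble::tibble(spectrum = seq_along(per), mape = per),
      summary = mape_summary(per),
      model_id = model_id, test_id = test_id, pred = pred
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<eval_report> %s on %s: mean MAPE %.3g%% [%.3g, %.3g], n = %d\n",
              x$model_id, x$test_id, s$mean_mape, s$ci_lo, s$ci_hi, s$n))
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_spectrum

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(model_id = x$model_id, test_id = x$test_id), x$summary
  )
}

#' Normalise an evaluation report by a baseline
#'
#' Dataset-modification studies report MAPE relative to the unmodified
#' baseline model on the same test spectra: values below 1 mark improved
#' accuracy, above 1 worsened accuracy.
#'
#' @param modified,baseline `eval_report`s over the same test set.
#' @return Tibble with `spectrum` and `normalized_mape`
#'   (modified / baseline, elementwise per test spectrum).
#' @export
normalize_report <- function(modified, baseline) {
  stopifnot(inherits(modified, "eval_report"), inherits(baseline, "eval_report"))
  if (!identical(modified$test_id, baseline$test_id) ||
      nrow(modified$per_spectrum) != nrow(baseline$per_spectrum)) {
    abort("reports were computed on different test sets.")
  }
  if (any(baseline$per_spectrum$mape <= 0)) {
    abort("baseline per-spectrum MAPE must be strictly positive.")
  }
  tibble::tibble(
    spectrum = modified$per_spectrum$spectrum,
    normalized_mape = modified$per_spectrum$mape / baseline$per_spectrum$mape
  )
}
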