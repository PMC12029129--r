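#' Scaled-down headline experiment
#'
#' The package's desk-scale counterpart of the flagship result: an
#' encoder-only transformer trained to quantify an 8-metabolite synthetic
#' library from fully augmented uniform-concentration mixtures, evaluated
#' as mean MAPE on 10 freshly simulated all-present uniform test spectra.
#' Sizes are scaled for a single CPU: an 11,500-point grid, 4,000
#' training plus 1,000 validation spectra, and a compact transformer
#' (bin 250, embedding 128, one encoder layer, four attention heads,
#' feedforward 256) trained with RAE and AdamW.
#'
#' @param seed Integer seed governing library synthesis, dataset
#'   generation, weight initialisation and test simulation.
#' @param n_spectra Training + validation spectra (split 80:20). The
#'   training set follows the standard uniform-dataset protocol: half the
#'   spectra contain every analyte, the other half leave each analyte
#'   out with probability 0.5.
#' @param n_test Test spectra (uniform, all analytes present, normalised
#'   by the training constant so intensities are on the scale the model
#'   was trained on).
#' @param n_points Grid points over -0.32 to 10.21 ppm.
#' @param n_metabolites Analytes in the synthetic library.
#' @param max_epochs Epoch cap of the training run.
#' @param learning_rate,effective_batch_size,accumulation_steps AdamW
#'   parameters.
#' @param verbose Print per-epoch losses?
#' @return List with `fit` (the `trained_model`), `report` (the
#'   `eval_report` on the test set), `mean_mape` (%), and `nnls_mape`
#'   (the non-negative least-squares baseline on the same test set, %).
#' @export
run_headline_experiment <- function(seed = 1, n_spectra = 5000L,
                                    n_test = 10L, n_points = 11500L,
                                    n_metabolites = 8L,
                                    max_epochs = 60L,
                                    learning_rate = 1e-3,
                                    effective_batch_size = 64L,
                                    accumulation_steps = 1L,
                                    verbose = FALSE) {
  grid <- ppm_grid(-0.32, 10.21, n_points)
  lib <- default_library(n_metabolites, field_strength = 400,
                         seed = seed, grid = grid)
  ds <- build_dataset(lib, n_spectra, sampler = conc_sampler("uniform"),
                      scheme = "half50", seed = seed + 1)
  cfg <- transformer_config(n_points, 250L, 128L, 4L, 1L, 256L, 1L,
                            n_metabolites)
  tc <- train_config(loss_spec("rae"), learning_rate = learning_rate,
                     effective_batch_size = effective_batch_size,
                     accumulation_steps = accumulation_steps,
                     patience = 50L, max_epochs = max_epochs,
                     seed = seed + 2)
  fit <- train_model(cfg, ds, tc, verbose = verbose)
  test <- build_dataset(lib, n_test, sampler = conc_sampler("uniform"),
                        scheme = "all_present", seed = seed + 3,
                        normalize = FALSE)
  test <- normalize_dataset(test, constant = ds$norm_constant)
  report <- evaluate_model(fit, test, model_id = "transformer-small",
                           test_id = "uniform-10")
  nnls <- nnls_quantify(test, lib)
  list(fit = fit, report = report,
       mean_mape = report$summary$mean_mape,
       nnls_mape = mean(mape_per_spectrum(nnls, test$truth)))
}
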