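# ggplot2 methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_pointrange labs
#'   theme_minimal facet_wrap geom_hline
#' @export
ggplot2::autoplot

#' @method autoplot ref_spectrum
#' @export
autoplot.ref_spectrum <- function(object, ...) {
  df <- tibble::tibble(ppm = ppm_points(object$grid),
                       intensity = object$intensity)
  ggplot(df, aes(.data$ppm, .data$intensity)) +
    geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    labs(x = "chemical shift (ppm)", y = "intensity (a.u.)",
         title = object$name) +
    theme_minimal()
}

#' @method autoplot mixture_spectrum
#' @export
autoplot.mixture_spectrum <- function(object, ...) {
  df <- tibble::tibble(ppm = ppm_points(object$grid),
                       intensity = object$intensity)
  ggplot(df, aes(.data$ppm, .data$intensity)) +
    geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    labs(x = "chemical shift (ppm)", y = "intensity (a.u.)") +
    theme_minimal()
}

#' @method autoplot spectral_dataset
#' @export
autoplot.spectral_dataset <- function(object, spectra = 1:min(3, nrow(object$spectra)), ...) {
  x <- ppm_points(object$grid)
  df <- purrr::map_dfr(spectra, function(i) {
    tibble::tibble(spectrum = factor(i), ppm = x,
                   intensity = object$spectra[i, ])
  })
  ggplot(df, aes(.data$ppm, .data$intensity)) +
    geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    facet_wrap(~spectrum, ncol = 1) +
    labs(x = "chemical shift (ppm)", y = "normalised intensity") +
    theme_minimal()
}

#' @method autoplot trained_model
#' @export
autoplot.trained_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot(df, aes(.data$epoch, .data$loss, colour = .data$set)) +
    geom_line() +
    ggplot2::scale_y_log10() +
    labs(x = "epoch", y = "loss", colour = NULL) +
    theme_minimal()
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  s <- glance(object)
  ggplot(s, aes(.data$model_id, .data$mean_mape)) +
    geom_pointrange(aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    labs(x = NULL, y = "mean MAPE (%)") +
    theme_minimal()
}

#' Compare evaluation reports as a point plot
#'
#' Mean MAPE with 95% confidence intervals for several reports on one
#' panel, the standard model-comparison display.
#'
#' @param reports List of `eval_report`s.
#' @return A ggplot object.
#' @export
plot_mape_comparison <- function(reports) {
  df <- purrr::map_dfr(reports, glance)
  ggplot(df, aes(.data$model_id, .data$mean_mape, colour = .data$test_id)) +
    geom_pointrange(aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                    position = ggplot2::position_dodge(width = 0.3)) +
    labs(x = NULL, y = "mean MAPE (%)", colour = "test set") +
    theme_minimal()
}
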