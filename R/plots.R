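#' Plot simulated or measured spectra
#'
#' @param spectra Spectra tibble.
#' @param alpha Line transparency.
#' @return A ggplot of absorbance against wavelength, one line per sample.
#' @export
plot_spectra <- function(spectra, alpha = 0.6) {
  long <- tidyr::pivot_longer(spectra, -"sample_id",
                              names_to = "wavelength_nm",
                              values_to = "absorbance") |>
    dplyr::mutate(wavelength_nm = as.numeric(.data$wavelength_nm))
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm, .data$absorbance,
                                     group = .data$sample_id)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.3) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.chemo_ejcr <- function(object, ...) {
  outline <- ejcr_outline(object)
  ggplot2::ggplot(outline, ggplot2::aes(.data$intercept, .data$slope)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = object$intercept, y = object$slope,
                      shape = 3) +
    ggplot2::annotate("point", x = 0, y = 1, colour = "red", shape = 4,
                      size = 3) +
    ggplot2::labs(x = "Intercept", y = "Slope",
                  title = sprintf("EJCR (%.0f%%), ideal point %s",
                                  (1 - object$alpha) * 100,
                                  if (object$contains_ideal) "inside"
                                  else "outside")) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.chemo_efa <- function(object, ...) {
  ggplot2::ggplot(object$traces,
                  ggplot2::aes(.data$window, .data$singular_value,
                               group = .data$factor)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~direction) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "Window size (rows)", y = "Singular value",
                  title = sprintf("EFA: estimated rank %d", object$rank)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.chemo_fedorov <- function(object, ...) {
  tr <- dplyr::mutate(object$trace,
                      step = dplyr::row_number(), .by = "restart")
  ggplot2::ggplot(tr, ggplot2::aes(.data$step, .data$det,
                                   group = .data$restart)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "Exchange step", y = "det(X'X)",
                  title = "Fedorov exchange determinant history") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.chemo_firefly <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$generation, .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Generation", y = "Best RMSECV (ug/mL)",
                  title = paste("Firefly convergence:", object$analyte)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.chemo_pcr <- function(object, ...) {
  ggplot2::ggplot(object$cv_curve,
                  ggplot2::aes(.data$k, .data$rmsecv,
                               colour = .data$analyte)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
    ggplot2::labs(x = "Components", y = "RMSECV (ug/mL)",
                  title = "PCR cross-validation curve") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.chemo_mcr <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$wavelength_nm, .data$absorptivity,
                               colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = "Resolved absorptivity",
                  title = sprintf("MCR-ALS resolved spectra (LOF %.3g%%)",
                                  object$lack_of_fit)) +
    ggplot2::theme_minimal()
}
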