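#' Plot a scattering spectrum
#'
#' @param spectrum A `spectrum` tibble (or several, as a named list).
#' @param rg_wavelengths Optional pair (red, green) to mark the RG
#'   evaluation wavelengths.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum, rg_wavelengths = NULL) {
  if (is.data.frame(spectrum)) spectrum <- list(spectrum = spectrum)
  df <- dplyr::bind_rows(spectrum, .id = "series")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$intensity,
                                        colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "scattering intensity (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(rg_wavelengths)) {
    p <- p + ggplot2::geom_vline(xintercept = rg_wavelengths,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot particle-height distributions
#'
#' @param ... Named histograms (tibbles with `z_nm`, `density`), e.g.
#'   `unbound = ..., bound = ...`.
#' @return A ggplot.
#' @export
plot_z_distribution <- function(...) {
  df <- dplyr::bind_rows(lapply(list(...), tibble::as_tibble), .id = "state")
  ggplot2::ggplot(df, ggplot2::aes(.data$z_nm, .data$density,
                                   fill = .data$state)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5, width = NULL) +
    ggplot2::labs(x = "z height (nm)", y = "probability density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Calibration-curve plot
#'
#' Replicate-mean RG with SD error bars against concentration (log x),
#' with the fitted ln-linear line.
#'
#' @param object A `calibration_fit` from [fit_calibration()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  stopifnot(!is.null(object$concentrations))
  df <- tibble::tibble(
    concentration = object$concentrations,
    rg = object$rg_means,
    sd = object$rg_sds
  )
  line <- tibble::tibble(
    concentration = exp(seq(log(min(df$concentration)),
                            log(max(df$concentration)), length.out = 100))
  )
  line$rg <- predict_rg(object, line$concentration)
  ggplot2::ggplot(df, ggplot2::aes(.data$concentration, .data$rg)) +
    ggplot2::geom_line(data = line, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rg - .data$sd,
                                          ymax = .data$rg + .data$sd)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "endotoxin concentration (EU/ml)", y = "RG ratio") +
    ggplot2::theme_minimal()
}

#' Plot a QCM trace with its annotated intervals
#'
#' @param trace A [qcm_trace()].
#' @return A ggplot.
#' @export
plot_qcm_trace <- function(trace) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$time_s, .data$delta_f_hz)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(Delta * f ~ "(Hz)")) +
    ggplot2::theme_minimal()
  ann <- attr(trace, "annotations")
  if (!is.null(ann)) {
    p <- p + ggplot2::geom_rect(
      data = ann, inherit.aes = FALSE, alpha = 0.12,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$label)) +
      ggplot2::labs(fill = NULL)
  }
  p
}

#' Overlay detections on a dark-field frame
#'
#' Renders the RGB frame as a raster with detection circles.
#'
#' @param image A [darkfield_image()].
#' @param detections A [detect_particles()] tibble.
#' @param gain Display gain applied before clipping to \[0, 1\].
#' @return A ggplot.
#' @export
plot_detections <- function(image, detections, gain = 2) {
  px <- pmin(image$pixels * gain, 1)
  h <- dim(px)[1]; w <- dim(px)[2]
  raster <- grDevices::rgb(px[, , 1], px[, , 2], px[, , 3])
  dim(raster) <- c(h, w)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = -0.5, xmax = w - 0.5,
                               ymin = -0.5, ymax = h - 0.5) +
    ggplot2::geom_point(data = detections,
                        ggplot2::aes(.data$x_px, .data$y_px),
                        shape = 1, colour = "white", size = 4) +
    ggplot2::coord_fixed(xlim = c(-0.5, w - 0.5), ylim = c(-0.5, h - 0.5)) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
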