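#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' spectra (value vs wavenumber, reversed axis as in FTIR convention),
#' complex reflection trajectories (secondary loops visible directly),
#' sensitivity maps (filled channel planes) and calibration fits.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name seiratcmt-plots
NULL

#' @rdname seiratcmt-plots
#' @export
autoplot.seira_spectrum <- function(object, ...) {
  ylab <- switch(spectrum_kind(object),
                 absorbance = "Absorbance A",
                 difference = expression(Delta * A),
                 baseline = "Baseline",
                 derivative1 = "dA/dw (per cm-1)",
                 derivative2 = "d2A/dw2 (per cm-2)")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavenumber, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Wavenumber (cm-1)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @rdname seiratcmt-plots
#' @export
autoplot.complex_trajectory <- function(object, ...) {
  df <- tibble(re = Re(object$r), im = Im(object$r),
               wavenumber = object$wavenumber)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$re, y = .data$im,
                                   colour = .data$wavenumber)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re r", y = "Im r", colour = "cm-1") +
    ggplot2::theme_minimal()
}

#' @rdname seiratcmt-plots
#' @export
autoplot.sensitivity_map <- function(object, ...) {
  axes <- attr(object, "axes")
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[axes[2]]],
                                       y = .data[[axes[1]]],
                                       fill = .data$i_seira)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "orangered", midpoint = 0) +
    ggplot2::labs(fill = "I_SEIRA") +
    ggplot2::theme_minimal()
}

#' @rdname seiratcmt-plots
#' @export
autoplot.calibration_fit <- function(object, ...) {
  grid <- seq(0, max(object$data$concentration), length.out = 200)
  p <- object$parameters
  yhat <- if (object$model == "linear") {
    p[["slope"]] * grid + p[["intercept"]]
  } else {
    p[["i_max"]] * (p[["k"]] * grid)^p[["n"]] / (1 + (p[["k"]] * grid)^p[["n"]])
  }
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = tibble(concentration = grid, signal = yhat)) +
    ggplot2::labs(x = sprintf("Concentration (%s)", object$units),
                  y = "Signal") +
    ggplot2::theme_minimal()
}
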