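#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an absorbance spectrum with the violet-contribution band
#'
#' @param object A [spectrum()].
#' @param vc_window Shaded violet-contribution window, nm.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum <- function(object, vc_window = c(500, 600), ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength_nm, .data$absorbance)) +
    ggplot2::annotate("rect", xmin = vc_window[1], xmax = vc_window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "purple") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance (AU)",
                  title = series_metadata(object)$fixture %||% NULL)
}

#' Plot a chromatogram
#' @param object A [chromatogram()].
#' @param peaks Optional peak table whose apexes are marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chromatogram <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (min)", y = "signal (mAU)")
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(
      data = peaks, ggplot2::aes(.data$apex_time_min, .data$apex_signal),
      colour = "red") +
      ggplot2::geom_text(
        data = peaks,
        ggplot2::aes(.data$apex_time_min, .data$apex_signal, label = .data$peak),
        vjust = -0.6, size = 3)
  }
  p
}

#' Plot a titration series with its fitted hydration sigmoid
#' @param object A titration series tibble.
#' @param fit Optional `"pkh_fit"`; drawn as a curve when supplied.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.titration_series <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$pH, .data$absorbance)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pH", y = "absorbance (AU)")
  if (!is.null(fit)) {
    grid <- tibble::tibble(pH = seq(min(object$pH), max(object$pH), length.out = 200))
    grid$absorbance <- fit$A0 / (1 + 10^(grid$pH - fit$estimate))
    p <- p + ggplot2::geom_line(data = grid, colour = "blue")
  }
  p
}

#' Plot colorant positions in the a*b* plane
#'
#' Mirrors the conventional presentation of colorimetry data: points in
#' a*b* space labelled by sample, with lightness mapped to point size.
#'
#' @param colors Tibble from [color_report()] rows.
#' @return A ggplot.
#' @export
plot_ab_plane <- function(colors) {
  ggplot2::ggplot(colors, ggplot2::aes(.data$a_star, .data$b_star,
                                       size = .data$L_star,
                                       label = .data$sample)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(size = 3, vjust = -1) +
    ggplot2::labs(x = "a*", y = "b*", size = "L*")
}
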