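# autoplot() methods for the package's result types.

#' Plot methods
#'
#' `autoplot()` methods: NND histograms, experimental-vs-null NND overlays,
#' site maps, aligned clouds and axial profiles, all returning ggplot
#' objects for further styling.
#'
#' @param object A package result object.
#' @param ... Unused.
#' @param binwidth Histogram bin width in nm.
#' @return A `ggplot` object.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @export
autoplot.nnd_result <- function(object, binwidth = 2.5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35",
                            color = "white") +
    ggplot2::labs(
      x = sprintf("%d. nearest-neighbor distance (nm)", object$k[1]),
      y = "sites"
    )
}

#' @rdname autoplot-methods
#' @export
autoplot.csr_comparison <- function(object, binwidth = 2.5, ...) {
  df <- tidy.csr_comparison(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, fill = .data$source)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      binwidth = binwidth, position = "identity", alpha = 0.55
    ) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::scale_fill_manual(
      values = c(experimental = "#c0392b", csr_null = "#16a0b0")
    ) +
    ggplot2::labs(
      x = sprintf("%d. nearest-neighbor distance (nm)", object$k),
      y = "density", fill = NULL,
      subtitle = sprintf("p = %.3g, excess below %g nm: %+.0f%%",
                         object$p_value, object$threshold,
                         100 * object$relative_excess)
    )
}

#' @rdname autoplot-methods
#' @export
autoplot.site_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' @rdname autoplot-methods
#' @export
autoplot.aligned_cloud <- function(object, binwidth = 1, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dx, y = .data$dy)) +
    ggplot2::geom_bin2d(binwidth = binwidth) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x offset (nm)", y = "y offset (nm)")
}

#' @rdname autoplot-methods
#' @export
autoplot.axial_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("window_center", "mean_z_a", "mean_z_b")],
    cols = c("mean_z_a", "mean_z_b"),
    names_to = "channel", values_to = "mean_z"
  )
  chans <- attr(object, "channels", exact = TRUE) %||% c("A", "B")
  long$channel <- ifelse(long$channel == "mean_z_a", chans[1], chans[2])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_center,
                                     y = .data$mean_z,
                                     color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "position along filament (nm)", y = "mean z (nm)",
                  color = NULL)
}

#' @rdname autoplot-methods
#' @export
autoplot.event_counts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_events)) +
    ggplot2::geom_bar(fill = "grey35") +
    ggplot2::labs(
      x = "binding events per site", y = "sites",
      subtitle = sprintf("dip = %.4f, p = %.3f",
                         attr(object, "dip", exact = TRUE),
                         attr(object, "p_value", exact = TRUE))
    )
}
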