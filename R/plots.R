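# ggplot2 displays for the scan's result types. Each plot_* function takes
# the corresponding tibble; autoplot methods dispatch on the classed objects.

#' Windowed track of a statistic along the genome
#'
#' @param windows tibble with `chrom`, `start`, and the statistic column.
#' @param stat column name to draw (e.g. `"fst"`, `"fd"`, `"pi_p1"`).
#' @returns A ggplot.
#' @export
plot_window_track <- function(windows, stat = "fst") {
  w <- as_tibble(windows)
  stopifnot(stat %in% names(w))
  ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                  y = .data[[stat]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "position (Mb)", y = stat) +
    ggplot2::theme_minimal()
}

#' Differentiation-vs-diversity-ratio outlier plot
#'
#' Scatter of window `log2(pi_P2/pi_P1)` against z-scored F_ST with the data
#' derived tail thresholds as dashed lines; Type 1 windows sit in the upper
#' right quadrant, Type 2 in the upper-left.
#'
#' @param classification result of [classify_windows()].
#' @returns A ggplot.
#' @export
plot_differentiation <- function(classification) {
  w <- classification$windows
  th <- classification$thresholds
  ggplot2::ggplot(w, ggplot2::aes(x = .data$log2_ratio, y = .data$z_fst,
                                  colour = .data$type)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = th$z_fst, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(th$log2_ratio_low, th$log2_ratio_high),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(Type1 = "#d95f02", Type2 = "#1b9e77",
                                            none = "grey60")) +
    ggplot2::labs(x = expression(log[2] * "(" * pi[P2] / pi[P1] * ")"),
                  y = expression(z(F[ST]))) +
    ggplot2::theme_minimal()
}

#' Decile boxplot analog: f_d distribution by F_ST decile
#'
#' @param deciles result of [decile_summary()].
#' @returns A ggplot (median and interquartile range per decile).
#' @export
plot_decile_fd <- function(deciles) {
  d <- deciles$deciles
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$decile), y = .data$fd_median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$fd_q1, ymax = .data$fd_q3),
                             na.rm = TRUE) +
    ggplot2::labs(x = expression("F"[ST] * " decile (1 = most differentiated)"),
                  y = expression("window f"[d])) +
    ggplot2::theme_minimal()
}

#' @rdname plot_window_track
#' @param object,... autoplot dispatch arguments.
#' @method autoplot introgression_windows
#' @export
autoplot.introgression_windows <- function(object, stat = "fd", ...) {
  plot_window_track(object, stat = stat)
}

#' @rdname plot_window_track
#' @method autoplot introscan_result
#' @export
autoplot.introscan_result <- function(object, stat = "fst", ...) {
  plot_window_track(tidy(object), stat = stat)
}
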