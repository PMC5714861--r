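#' Plot a windowed recombination-frequency track
#'
#' @param track A tibble from [windowed_recfreq()].
#' @return A ggplot: cM/Mb along each chromosome, one facet per chromosome.
#' @export
plot_recfreq <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$start_mb, y = .data$freq_cm_mb)) +
    ggplot2::geom_step(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Recombination frequency (cM/Mb)") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of per-line recombination events
#'
#' @param bps A `breakpoint_set`, or a tibble from [events_per_line()].
#' @return A ggplot histogram of events per line.
#' @export
plot_event_distribution <- function(bps) {
  ev <- if (inherits(bps, "breakpoint_set")) events_per_line(bps) else bps
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$events)) +
    ggplot2::geom_histogram(bins = 30, fill = "#41ab5d", colour = "white") +
    ggplot2::labs(x = "Recombination events per line", y = "Lines") +
    ggplot2::theme_minimal()
}

#' Plot resampled bin statistics against marker and line numbers
#'
#' @param grid A tibble from [resample_bins()].
#' @param stat Which statistic to show (`"bin_number"` or
#'   `"mean_bin_size_mb"`).
#' @return A ggplot with one line per line-count, mean +/- sd ribbons.
#' @export
plot_bin_resample <- function(grid, stat = c("bin_number", "mean_bin_size_mb")) {
  stat <- match.arg(stat)
  d <- grid[grid$stat == stat, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_markers, y = .data$mean,
                                  colour = factor(.data$n_lines),
                                  group = factor(.data$n_lines))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd,
                                      fill = factor(.data$n_lines)),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Markers", y = stat, colour = "Lines", fill = "Lines") +
    ggplot2::theme_minimal()
}

#' Plot a LOD profile with optional QTL calls
#'
#' @param profile A tibble from [scan_lod()] (one or a few traits).
#' @param calls Optional tibble from [call_qtl()]; support intervals are
#'   shaded.
#' @return A ggplot faceted by chromosome.
#' @export
plot_lod_profile <- function(profile, calls = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$pos_mb, y = .data$lod,
                                             colour = .data$trait)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    p <- p + ggplot2::geom_rect(
      data = calls,
      ggplot2::aes(xmin = .data$start_mb, xmax = .data$end_mb),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "#fd8d3c",
      inherit.aes = FALSE
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a power-law fit
#'
#' @param object A [fit_power_law()] object.
#' @param ... Unused.
#' @return A ggplot of the data and fitted curve on log-log axes.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  d <- object$data
  curve <- tibble(
    x = exp(seq(log(min(d$x)), log(max(d$x)), length.out = 100))
  )
  curve$y <- predict(object, curve)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "#e6550d") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "X", y = "Y",
                  subtitle = sprintf("Y = %.3g * X^%.3g",
                                     coef(object)["m"], coef(object)["n"])) +
    ggplot2::theme_minimal()
}
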