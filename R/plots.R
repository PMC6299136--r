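# ggplot2 display helpers for the main result types.

#' Plot a hypnogram as a state ribbon
#' @param hyp hypnogram tibble.
#' @return a ggplot.
#' @export
plot_hypnogram <- function(hyp) {
  ggplot2::ggplot(hyp) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_s / 60,
                                    xmax = .data$end_s / 60,
                                    ymin = 0, ymax = 1,
                                    fill = .data$state)) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (min)", y = NULL, fill = "state") +
    ggplot2::theme_minimal()
}

#' Plot the active-voxel fraction with detected surges shaded
#' @param trace tibble from [activity_trace()].
#' @param surges surge tibble from [detect_surges()].
#' @param ratio_thr threshold line to draw (default 0.5).
#' @return a ggplot.
#' @export
plot_surges <- function(trace, surges, ratio_thr = 0.5) {
  g <- ggplot2::ggplot(trace) +
    ggplot2::geom_line(ggplot2::aes(x = .data$time_s / 60,
                                    y = .data$active_fraction),
                       colour = "grey40") +
    ggplot2::geom_hline(yintercept = ratio_thr, linetype = 2) +
    ggplot2::labs(x = "time (min)", y = "active voxel fraction") +
    ggplot2::theme_minimal()
  if (nrow(surges) > 0) {
    g <- g + ggplot2::geom_rect(
      data = surges,
      ggplot2::aes(xmin = .data$start_s / 60, xmax = .data$end_s / 60,
                   ymin = 0, ymax = 1),
      fill = "red", alpha = 0.2, inherit.aes = FALSE)
  }
  g
}

#' @export
autoplot.crosscorrelogram <- function(object, ...) {
  ggplot2::ggplot(object$by_episode,
                  ggplot2::aes(x = .data$lag_s, y = .data$r,
                               group = .data$episode)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(data = object$mean_correlogram,
                       ggplot2::aes(group = NULL), colour = "red",
                       linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$mean_peak_lag_s,
                        linetype = 2) +
    ggplot2::labs(x = "lag (s; positive = LFP leads CBV)", y = "Pearson r") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$region_a, y = .data$region_b,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "blue",
                                  mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Connectivity, ", object$state)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.pac_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$phase_deg, y = .data$mean_power)) +
    ggplot2::geom_col(width = 360 / nrow(object$profile), fill = "grey30") +
    ggplot2::labs(x = "theta phase (deg; 0 = trough)",
                  y = "mean band power") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
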