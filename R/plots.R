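# ggplot2 graphics for fields, trajectories and heading distributions.

#' Plot an odour landscape
#'
#' Raster of the analytic concentration field, with the source marked.
#'
#' @param field an `odour_field`.
#' @inheritParams field_raster
#' @return a ggplot object.
#' @export
plot_field <- function(field, xlim = c(-15, 15), ylim = c(-15, 15), n = 101) {
  grid <- field_raster(field, xlim = xlim, ylim = ylim, n = n)
  ggplot2::ggplot(grid, ggplot2::aes(.data$x, .data$y,
                                     fill = .data$concentration)) +
    ggplot2::geom_raster() +
    ggplot2::annotate("point", x = field$source[1], y = field$source[2],
                      shape = 4, colour = "white", size = 2) +
    ggplot2::scale_fill_viridis_c(name = "odour (a.u.)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_cx_trajectories
#' @param trajectories a `cx_trajectories` tibble.
#' @export
plot_trajectories <- function(trajectories) {
  ggplot2::autoplot(trajectories)
}

#' Plot trajectories of an experiment run
#'
#' Paths of every agent, coloured by behavioural mode, facetted by run.
#'
#' @param object a `cx_trajectories` tibble.
#' @param ... ignored.
#' @return a ggplot object.
#' @name autoplot_cx_trajectories
#' @method autoplot cx_trajectories
#' @export
autoplot.cx_trajectories <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       group = .data$agent)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$mode), linewidth = 0.3,
                       na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$run), labeller = "label_both") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", colour = "mode") +
    ggplot2::theme_minimal()
}

#' Rose plot of headings
#'
#' Circular histogram of a set of headings (radians), e.g. the settled
#' headings of a manoeuvre experiment.
#'
#' @param headings numeric vector of angles in radians.
#' @param bins number of angular bins.
#' @return a ggplot object.
#' @export
plot_heading_rose <- function(headings, bins = 16) {
  df <- tibble::tibble(heading_deg = (rad2deg(headings) %% 360))
  ggplot2::ggplot(df, ggplot2::aes(.data$heading_deg)) +
    ggplot2::geom_histogram(breaks = seq(0, 360, length.out = bins + 1),
                            fill = "steelblue", colour = "white") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}

#' Upwind speed and angular velocity time series
#'
#' The per-step metric panels of the anemotaxis experiments: upwind
#' translational speed and unsigned angular velocity against time, one line
#' per agent.
#'
#' @param metrics a [compute_metrics()] result.
#' @return a ggplot object.
#' @export
plot_metrics_timeseries <- function(metrics) {
  stopifnot(inherits(metrics, "cx_metrics"))
  long <- tidyr::pivot_longer(
    metrics$steps,
    cols = c("upwind_speed", "angular_velocity"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                     group = interaction(.data$run,
                                                         .data$agent))) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "step", y = NULL) +
    ggplot2::theme_minimal()
}
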