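#' Summary metrics of a trajectory set
#'
#' Computes the per-step and per-agent tables used to summarise the
#' behavioural experiments:
#'
#' * the **steps** table holds, for every recorded step, the upwind speed
#'   (velocity component along the direction the wind blows *from*,
#'   `-theta_w`; arena units per step) and the unsigned angular velocity
#'   (radians per step), when a wind direction is available;
#' * the **agents** table holds one row per (run, agent): final position and
#'   concentration, net displacement from start, and - when a goal is known
#'   (the nest for homing runs) - the final distance to the goal, the arrival
#'   time (first step within `radius` of it, `NA` if never) and the path
#'   length walked up to arrival (total walked length if the goal is never
#'   reached).
#'
#' Circular quantities use standard vector-mean definitions (see
#' [circular_mean()]).
#'
#' @param trajectories a `cx_trajectories` tibble.
#' @param theta_w wind direction override (radians); defaults to the value
#'   in the trajectory set's configuration, if any.
#' @param goal optional 2-element goal position; defaults to the odour
#'   source (the nest) for ant homing runs.
#' @param radius arrival radius around the goal (arena units).
#' @return an object of class `cx_metrics`: a list with tibbles `steps` and
#'   `agents`.
#' @export
compute_metrics <- function(trajectories, theta_w = NULL, goal = NULL,
                            radius = NULL) {
  stopifnot(inherits(trajectories, "cx_trajectories"), nrow(trajectories) > 0)
  config <- attr(trajectories, "config")
  if (is.null(theta_w) && !is.null(config$w_theta)) theta_w <- config$w_theta
  if (is.null(goal) && identical(attr(trajectories, "experiment"), "ant_homing")) {
    goal <- c(0, 0)
  }
  if (is.null(radius)) {
    radius <- if (!is.null(config$arrival_radius)) config$arrival_radius else 0.5
  }

  steps <- trajectories |>
    dplyr::group_by(.data$run, .data$agent) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(
      vx = .data$x - dplyr::lag(.data$x),
      vy = .data$y - dplyr::lag(.data$y),
      angular_velocity = abs(wrap_angle(.data$heading - dplyr::lag(.data$heading)))
    ) |>
    dplyr::filter(!is.na(.data$vx)) |>
    dplyr::ungroup()
  steps$upwind_speed <- if (!is.null(theta_w)) {
    -cos(theta_w) * steps$vx - sin(theta_w) * steps$vy
  } else {
    NA_real_
  }
  steps <- dplyr::select(
    steps, "run", "agent", "t", "mode",
    "upwind_speed", "angular_velocity"
  )

  agents <- trajectories |>
    dplyr::group_by(.data$run, .data$agent) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::summarise(
      steps = max(.data$t),
      final_x = dplyr::last(.data$x),
      final_y = dplyr::last(.data$y),
      final_heading = dplyr::last(.data$heading),
      final_concentration = dplyr::last(.data$concentration),
      net_displacement = sqrt((dplyr::last(.data$x) - dplyr::first(.data$x))^2 +
                                (dplyr::last(.data$y) - dplyr::first(.data$y))^2),
      .groups = "drop"
    )
  if (!is.null(goal)) {
    sl <- config$sl
    arrivals <- trajectories |>
      dplyr::group_by(.data$run, .data$agent) |>
      dplyr::arrange(.data$t, .by_group = TRUE) |>
      dplyr::summarise(
        goal_distance = sqrt((dplyr::last(.data$x) - goal[1])^2 +
                               (dplyr::last(.data$y) - goal[2])^2),
        arrival_t = {
          d <- sqrt((.data$x - goal[1])^2 + (.data$y - goal[2])^2)
          hit <- which(d <= radius)
          if (length(hit)) .data$t[hit[1]] else NA_real_
        },
        .groups = "drop"
      )
    arrivals$path_length <- sl * dplyr::coalesce(arrivals$arrival_t,
                                                 as.numeric(max(trajectories$t)))
    agents <- dplyr::left_join(agents, arrivals, by = c("run", "agent"))
  }
  structure(list(steps = steps, agents = agents), class = "cx_metrics")
}

#' Group heading at a time point
#'
#' Circular mean (and resultant length) of the agents' headings at step `at`
#' across all runs of a trajectory set - the group-heading summary reported
#' for the homing experiments.
#'
#' @param trajectories a `cx_trajectories` tibble.
#' @param at time step at which to read the headings.
#' @return list with `mean` (radians) and `resultant` (in `[0, 1]`).
#' @export
group_heading <- function(trajectories, at) {
  h <- trajectories$heading[trajectories$t == at]
  if (!length(h)) stop("no recorded step t = ", at, call. = FALSE)
  circular_mean(h)
}

#' @export
print.cx_metrics <- function(x, ...) {
  cat("<cx_metrics>\n")
  cat("steps:", nrow(x$steps), "rows\n")
  print(x$agents, ...)
  invisible(x)
}
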