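# broom-style tidiers for trajectory sets.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory set into per-agent summaries
#'
#' One row per (run, agent) with the endpoint and path summaries from
#' [compute_metrics()].
#'
#' @param x a `cx_trajectories` tibble.
#' @param ... ignored.
#' @return a tibble.
#' @method tidy cx_trajectories
#' @export
tidy.cx_trajectories <- function(x, ...) {
  compute_metrics(x)$agents
}

#' One-row summary of a trajectory set
#'
#' @param x a `cx_trajectories` tibble.
#' @param ... ignored.
#' @return a one-row tibble with the experiment name, seed, agent/run counts
#'   and run length.
#' @method glance cx_trajectories
#' @export
glance.cx_trajectories <- function(x, ...) {
  config <- attr(x, "config")
  tibble::tibble(
    experiment = attr(x, "experiment"),
    preset = config$name %||% NA_character_,
    seed = attr(x, "seed"),
    n_runs = dplyr::n_distinct(x$run),
    n_agents = dplyr::n_distinct(x$run, x$agent),
    steps = max(x$t),
    sl = config$sl
  )
}
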