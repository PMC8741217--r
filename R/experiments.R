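# Experiment runners: seeded agent loops over the odour worlds, returning
# tidy trajectory tibbles (class cx_trajectories).

# derive an independent, reproducible RNG seed per (run, agent) so that
# shrinking the agent count reproduces a prefix-subset of the full run
seed_for <- function(seed, run, agent) {
  (as.integer(seed) %% 1000000L) + 7919L * as.integer(run) +
    104729L * as.integer(agent)
}

clamp_turn <- function(turn, cap) max(-cap, min(cap, turn))

# preallocated per-agent trail; row t = state *before* step t, plus the
# sensory sample, mode and turn of that step; final row holds the terminal
# pose (mode/turn NA)
new_trail <- function(steps) {
  n <- steps + 1L
  list(
    t = 0:steps,
    x = numeric(n), y = numeric(n), heading = numeric(n),
    concentration = numeric(n), delta_c = numeric(n),
    mode = rep(NA_character_, n), turn = rep(NA_real_, n)
  )
}

trail_tibble <- function(trail, run, agent) {
  tibble::tibble(
    run = run, agent = agent, t = trail$t,
    x = trail$x, y = trail$y, heading = trail$heading,
    concentration = trail$concentration, delta_c = trail$delta_c,
    mode = trail$mode, turn = trail$turn
  )
}

new_trajectories <- function(rows, config, seed, experiment) {
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cx_trajectories", class(out))
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "experiment") <- experiment
  out
}

config_fields <- function(config) {
  if (config$kind %in% c("volcano", "linear")) {
    list(gradient_field(config$kind, k = config$k, tau = config$tau,
                        r = config$r))
  } else {
    fields <- list(plume_field(
      q = config$q, u = config$u, theta_w = config$w_theta,
      ks = config$ks, eps = config$sl
    ))
    d <- config$distractor
    if (!is.null(d) && isTRUE(d$enabled)) {
      fields <- c(fields, list(plume_field(
        q = d$q, u = config$u, theta_w = config$w_theta,
        ks = config$ks, source = c(d$x, d$y), eps = config$sl
      )))
    }
    fields
  }
}

sum_concentration <- function(fields, pos) {
  sum(vapply(fields, concentration_at, numeric(1), pos = pos))
}

#' Fly chemotaxis experiment
#'
#' Releases agents with random headings from random start locations in the
#' start zone of a windless gradient landscape and drives each purely by the
#' chemotaxis copy-and-shift rule for the configured number of steps. The
#' default preset follows the study conditions: 5 agents, 1500 steps,
#' 4 repeats, start zone (-12, 12) x (-12, 12).
#'
#' @param config an experiment configuration (see [cx_presets()] /
#'   [load_config()]); must use a `"volcano"` or `"linear"` landscape.
#' @param seed integer seed governing all randomness; defaults to
#'   `config$seed`.
#' @return a `cx_trajectories` tibble with columns
#'   `run, agent, t, x, y, heading, concentration, delta_c, mode, turn`.
#' @export
run_chemotaxis_experiment <- function(config, seed = NULL) {
  config <- validate_config(config)
  stopifnot(config$kind %in% c("volcano", "linear"))
  if (is.null(seed)) seed <- config$seed
  field <- config_fields(config)[[1]]
  zone <- config$start_zone
  rows <- list()
  for (run in seq_len(config$n_repeats)) {
    for (ag in seq_len(config$n_agents)) {
      set.seed(seed_for(seed, run, ag))
      agent <- agent_state(
        position = c(stats::runif(1, zone$xmin, zone$xmax),
                     stats::runif(1, zone$ymin, zone$ymax)),
        heading = stats::runif(1, 0, 2 * pi),
        sl = config$sl
      )
      trail <- new_trail(config$steps)
      prev <- NULL
      for (t in seq_len(config$steps)) {
        smp <- sample_with_memory(field, agent$position, prev)
        compass <- encode_heading(agent$heading, config$compass_amp)
        desired <- chemotaxis_heading(
          compass, smp$delta, k_chemo = config$k_chemo,
          direction = config$chemo_direction,
          sign_convention = config$chemo_sign,
          min_shift_cols = config$chemo_min_shift,
          interp = config$interp
        )
        st <- steer(desired, compass, k_motor = config$k_motor,
                    offset_cols = config$offset_cols)
        turn <- clamp_turn(st$turn_angle, config$turn_cap)
        trail$x[t] <- agent$position[1]; trail$y[t] <- agent$position[2]
        trail$heading[t] <- agent$heading
        trail$concentration[t] <- smp$concentration
        trail$delta_c[t] <- smp$delta
        trail$mode[t] <- "OFF"; trail$turn[t] <- turn
        agent <- step_agent(agent, turn, turn_cap = config$turn_cap)
        prev <- smp$concentration
      }
      last <- config$steps + 1L
      trail$x[last] <- agent$position[1]; trail$y[last] <- agent$position[2]
      trail$heading[last] <- agent$heading
      fin <- sample_with_memory(field, agent$position, prev)
      trail$concentration[last] <- fin$concentration
      trail$delta_c[last] <- fin$delta
      rows[[length(rows) + 1L]] <- trail_tibble(trail, run, ag)
    }
  }
  new_trajectories(rows, config, seed, "chemotaxis")
}

# shared plume loop for the anemotaxis and integrated fly experiments;
# `classify` maps (gated concentration, delta, gate_on) -> mode
run_plume_fly <- function(config, seed, experiment, classify) {
  stopifnot(config$kind == "plume")
  fields <- config_fields(config)
  zone <- config$start_zone
  gate_on <- function(t) {
    w <- config$odour_window
    if (is.null(w)) TRUE else (t > w[1] * config$steps && t <= w[2] * config$steps)
  }
  rows <- list()
  for (run in seq_len(config$n_repeats)) {
    for (ag in seq_len(config$n_agents)) {
      set.seed(seed_for(seed, run, ag))
      agent <- agent_state(
        position = c(stats::runif(1, zone$xmin, zone$xmax),
                     stats::runif(1, zone$ymin, zone$ymax)),
        heading = stats::runif(1, 0, 2 * pi),
        sl = config$sl
      )
      trail <- new_trail(config$steps)
      prev <- 0
      for (t in seq_len(config$steps)) {
        gate <- gate_on(t)
        conc <- if (gate) sum_concentration(fields, agent$position) else 0
        delta <- conc - prev
        mode <- classify(conc, delta, gate)
        compass <- encode_heading(agent$heading, config$compass_amp)
        desired <- switch(mode,
          ON = anemotaxis_heading(
            compass, wpn_response(config$w_theta, agent$heading),
            interp = config$interp
          ),
          OFF = chemotaxis_heading(
            compass, delta, k_chemo = config$k_chemo,
            direction = config$chemo_direction,
            sign_convention = config$chemo_sign,
            min_shift_cols = config$chemo_min_shift, interp = config$interp
          ),
          RANDOM = random_heading(agent$heading, jitter = config$jitter,
                                  amplitude = config$compass_amp)
        )
        st <- steer(desired, compass, k_motor = config$k_motor,
                    offset_cols = config$offset_cols)
        turn <- clamp_turn(st$turn_angle, config$turn_cap)
        trail$x[t] <- agent$position[1]; trail$y[t] <- agent$position[2]
        trail$heading[t] <- agent$heading
        trail$concentration[t] <- conc; trail$delta_c[t] <- delta
        trail$mode[t] <- mode; trail$turn[t] <- turn
        agent <- step_agent(agent, turn, turn_cap = config$turn_cap)
        prev <- conc
      }
      last <- config$steps + 1L
      trail$x[last] <- agent$position[1]; trail$y[last] <- agent$position[2]
      trail$heading[last] <- agent$heading
      g <- gate_on(config$steps + 1L)
      trail$concentration[last] <-
        if (g) sum_concentration(fields, agent$position) else 0
      trail$delta_c[last] <- trail$concentration[last] - prev
      rows[[length(rows) + 1L]] <- trail_tibble(trail, run, ag)
    }
  }
  new_trajectories(rows, config, seed, experiment)
}

#' Fly odour-gated anemotaxis experiment
#'
#' Agents in a constant-wind Gaussian plume with the rewarding odour toggled
#' ON only during the second quarter of the run (steps `(T/4, T/2]`). While
#' the odour is ON the desired heading is the WPN-shifted upwind ring (surge
#' upwind); while it is OFF the agent walks a correlated random walk. The
#' default preset: 4 agents, 200 steps, 5 repeats, start zone
#' (-1.5, 1.5) x (-13, -5).
#'
#' @inheritParams run_chemotaxis_experiment
#' @return a `cx_trajectories` tibble.
#' @export
run_anemotaxis_experiment <- function(config, seed = NULL) {
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$seed
  run_plume_fly(config, seed, "anemotaxis",
                classify = function(conc, delta, gate) {
                  if (gate) "ON" else "RANDOM"
                })
}

#' Fly integrated ON/OFF-response experiment
#'
#' Same world and schedule as the anemotaxis experiment, but the behavioural
#' mode is selected each step by the ON/OFF switching truth table applied to
#' the sensed concentration and its change: ON engages upwind anemotaxis,
#' OFF engages chemotaxis, RANDOM a correlated random walk. Mode transitions
#' are visible in the `mode` column of the returned trajectories.
#'
#' @inheritParams run_chemotaxis_experiment
#' @return a `cx_trajectories` tibble.
#' @export
run_fly_integrated_experiment <- function(config, seed = NULL) {
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$seed
  thr <- switch_thresholds(config$thr_o, config$thr_on, config$thr_off)
  run_plume_fly(config, seed, "fly_integrated",
                classify = function(conc, delta, gate) {
                  classify_response(conc, delta, thr)
                })
}

#' Ant homing experiment: path integration integrated with olfaction
#'
#' Full-vector ants (home vector of the configured length and direction) are
#' released at each release point with uniformly random initial headings.
#' Each step the switching circuit classifies the odour signal, the
#' mode-gated olfactory desired heading is weighted by `k_o` times the
#' concentration and integrated with the fading path-integration ring by the
#' ring attractor, and the settled bump is steered against the compass. An
#' optional conspecific-nest distractor plume is added to the home-nest
#' plume. When the integrated ring carries no appreciable direction (path
#' integrator spent and no odour), the RANDOM-mode jitter is applied
#' directly so lost agents search instead of walking straight.
#'
#' Runs are indexed by release point; `config$n_agents` agents start from
#' each.
#'
#' @inheritParams run_chemotaxis_experiment
#' @return a `cx_trajectories` tibble.
#' @export
run_ant_homing_experiment <- function(config, seed = NULL) {
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$seed
  stopifnot(config$kind == "plume")
  fields <- config_fields(config)
  thr <- switch_thresholds(config$thr_o, config$thr_on, config$thr_off)
  ra0 <- do.call(ring_attractor, config$ra)
  rows <- list()
  for (rp in seq_along(config$release_points)) {
    release <- config$release_points[[rp]]
    for (ag in seq_len(config$n_agents)) {
      set.seed(seed_for(seed, rp, ag))
      agent <- agent_state(
        position = release,
        heading = stats::runif(1, 0, 2 * pi),
        sl = config$sl
      )
      memory <- pi_memory(config$pi_length, config$pi_direction)
      ra <- ra0
      trail <- new_trail(config$steps)
      prev <- 0
      for (t in seq_len(config$steps)) {
        conc <- sum_concentration(fields, agent$position)
        delta <- conc - prev
        mode <- classify_response(conc, delta, thr)
        compass <- encode_heading(agent$heading, config$compass_amp)
        chemo <- chemotaxis_heading(
          compass, delta, k_chemo = config$k_chemo,
          direction = config$chemo_direction,
          sign_convention = config$chemo_sign,
          min_shift_cols = config$chemo_min_shift, interp = config$interp
        )
        anemo <- anemotaxis_heading(
          compass, wpn_response(config$w_theta, agent$heading),
          interp = config$interp
        )
        out <- integrate_pi_olfaction(
          config$compass_amp * pi_ring(memory), mode, chemo, anemo, conc,
          k_o = config$k_o, ra = ra, reset = FALSE
        )
        ra <- out$attractor
        dec <- decode_ring(out$ring)
        turn <- if (is.na(dec$theta) ||
                    dec$magnitude < 0.05 * config$compass_amp) {
          stats::runif(1, -config$jitter, config$jitter)
        } else {
          clamp_turn(
            project_to_steering(out$ring, compass,
                                k_motor = config$k_motor,
                                offset_cols = config$offset_cols)$turn_angle,
            config$turn_cap
          )
        }
        trail$x[t] <- agent$position[1]; trail$y[t] <- agent$position[2]
        trail$heading[t] <- agent$heading
        trail$concentration[t] <- conc; trail$delta_c[t] <- delta
        trail$mode[t] <- mode; trail$turn[t] <- turn
        before <- agent$position
        agent <- step_agent(agent, turn, turn_cap = config$turn_cap)
        memory <- pi_update(memory, agent$position - before)
        prev <- conc
      }
      last <- config$steps + 1L
      trail$x[last] <- agent$position[1]; trail$y[last] <- agent$position[2]
      trail$heading[last] <- agent$heading
      trail$concentration[last] <- sum_concentration(fields, agent$position)
      trail$delta_c[last] <- trail$concentration[last] - prev
      rows[[length(rows) + 1L]] <- trail_tibble(trail, rp, ag)
    }
  }
  new_trajectories(rows, config, seed, "ant_homing")
}

#' Ant manoeuvre experiments: wind compensation and backtracking
#'
#' Forms the working-memory desired heading at a scripted trigger - the
#' clutch instant for wind compensation (compass copy shifted by the
#' WPN-encoded egocentric upwind angle) or the capture instant for
#' backtracking (constant 180-degree shift) - then releases agents at the
#' release point with uniformly random initial headings, steering from the
#' stored memory alone. The distribution of headings after a settling window
#' concentrates on the stored direction.
#'
#' @inheritParams run_chemotaxis_experiment
#' @param kind `"wind_compensation"` or `"backtracking"`.
#' @return a `cx_trajectories` tibble; the decoded memory direction is
#'   stored in the `memory_direction` attribute.
#' @export
run_manoeuvre_experiment <- function(config, kind = c("wind_compensation",
                                                      "backtracking"),
                                     seed = NULL) {
  kind <- match.arg(kind)
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$seed
  compass_capture <- encode_heading(config$capture_heading, config$compass_amp)
  memory <- if (kind == "wind_compensation") {
    form_wind_compensation_memory(
      compass_capture,
      wpn_response(config$w_theta, config$capture_heading),
      formed_at = 0L, interp = config$interp
    )
  } else {
    form_backtracking_memory(compass_capture, formed_at = 0L,
                             interp = config$interp)
  }
  rows <- list()
  for (ag in seq_len(config$n_agents)) {
    set.seed(seed_for(seed, 1L, ag))
    agent <- agent_state(
      position = config$release_point,
      heading = stats::runif(1, 0, 2 * pi),
      sl = config$sl
    )
    trail <- new_trail(config$steps)
    for (t in seq_len(config$steps)) {
      compass <- encode_heading(agent$heading, config$compass_amp)
      st <- navigate_from_memory(memory, compass,
                                 k_motor = config$k_motor,
                                 offset_cols = config$offset_cols)
      turn <- clamp_turn(st$turn_angle, config$turn_cap)
      trail$x[t] <- agent$position[1]; trail$y[t] <- agent$position[2]
      trail$heading[t] <- agent$heading
      trail$concentration[t] <- NA_real_; trail$delta_c[t] <- NA_real_
      trail$mode[t] <- kind; trail$turn[t] <- turn
      agent <- step_agent(agent, turn, turn_cap = config$turn_cap)
    }
    last <- config$steps + 1L
    trail$x[last] <- agent$position[1]; trail$y[last] <- agent$position[2]
    trail$heading[last] <- agent$heading
    trail$concentration[last] <- NA_real_; trail$delta_c[last] <- NA_real_
    rows[[length(rows) + 1L]] <- trail_tibble(trail, 1L, ag)
  }
  out <- new_trajectories(rows, config, seed, kind)
  attr(out, "memory_direction") <- decode_ring(memory$ring)$theta
  out
}

#' Write a trajectory set to CSV
#'
#' Plain deterministic CSV export (columns
#' `run, agent, t, x, y, heading, concentration, delta_c, mode, turn`): the
#' same (config, seed) pair produces byte-identical files.
#'
#' @param trajectories a `cx_trajectories` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(as.data.frame(trajectories), path, row.names = FALSE)
  invisible(path)
}
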