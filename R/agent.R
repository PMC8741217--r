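#' Agent kinematic state
#'
#' A point agent moving at constant speed: one step of fixed length `sl` is
#' taken along the (updated) heading at every time step, so
#' `|P[t+1] - P[t]| = sl` exactly. The turn produced by the steering circuit
#' is applied as an increment to the running heading.
#'
#' @param position 2-element start position (arena units).
#' @param heading initial heading (radians, world frame).
#' @param sl step length per time step (arena units).
#' @return an `agent_state` object.
#' @export
agent_state <- function(position, heading, sl) {
  stopifnot(length(position) == 2, all(is.finite(position)),
            is.finite(heading), sl > 0)
  structure(
    list(position = as.numeric(position), heading = wrap_angle(heading), sl = sl),
    class = "agent_state"
  )
}

#' Advance an agent by one step
#'
#' Adds the turn to the heading (wrapped), optionally capped at
#' `turn_cap` per step to prevent numerical spin at extreme steering
#' imbalances, then moves one step length along the new heading.
#'
#' @param agent an [agent_state()] object.
#' @param turn turn increment (radians) from the steering circuit.
#' @param turn_cap per-step cap on `|turn|` (radians); `Inf` disables it.
#' @return the updated `agent_state`.
#' @export
step_agent <- function(agent, turn, turn_cap = pi / 2) {
  stopifnot(inherits(agent, "agent_state"), is.finite(turn))
  turn <- max(-turn_cap, min(turn_cap, turn))
  agent$heading <- wrap_angle(agent$heading + turn)
  agent$position <- agent$position +
    agent$sl * c(cos(agent$heading), sin(agent$heading))
  agent
}
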