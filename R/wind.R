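#' Wind-projection-neuron (WPN) response
#'
#' Encodes the wind direction relative to the animal's body axis as sensed by
#' antennal deflection. The WPN rate is the difference between the two
#' antennal projection pathways,
#' `wpn = sin(theta_w - theta_h + pi) - sin(-(theta_w - theta_h + pi))
#'      = 2 sin(theta_w - theta_h + pi)`,
#' where `theta_w` is the direction the air flows *toward* and `theta_h` the
#' current heading. The scalar rate is sign-degenerate (it cannot distinguish
#' a wind at +x from -x relative to the body), so the output also carries the
#' unambiguous egocentric upwind angle, `(theta_w + pi) - theta_h` wrapped to
#' `(-pi, pi]` - the direction the wind comes *from*, in body coordinates -
#' which is what drives the copy-and-shift of the upwind desired heading.
#'
#' @param theta_w wind direction (direction of airflow), radians, world frame.
#' @param theta_h current heading, radians, world frame.
#' @return list with `wpn` (scalar firing, a.u.) and
#'   `egocentric_upwind_angle` (radians, `(-pi, pi]`).
#' @examples
#' wpn_response(theta_w = -pi / 2, theta_h = pi / 2) # heading straight upwind
#' @export
wpn_response <- function(theta_w, theta_h) {
  stopifnot(is.finite(theta_w), is.finite(theta_h))
  d <- theta_w - theta_h + pi
  list(
    wpn = sin(d) - sin(-d),
    egocentric_upwind_angle = wrap_angle(theta_w + pi - theta_h)
  )
}

#' Upwind desired-heading ring
#'
#' Copies the current-heading compass bump and shifts it by the egocentric
#' upwind angle reported by the WPN pathway, yielding a desired heading that
#' decodes to the geocentric upwind direction (`theta_w + pi`) regardless of
#' the current heading, up to the 4.5-degree shift quantisation.
#'
#' @param current current-heading ring (8 activations).
#' @param wind a [wpn_response()] result.
#' @inheritParams copy_and_shift
#' @return heading ring encoding the upwind direction.
#' @export
upwind_ring <- function(current, wind, interp = c("fourier", "linear")) {
  copy_and_shift(current, wind$egocentric_upwind_angle, interp = match.arg(interp))
}
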