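#' Thresholds of the ON/OFF switching circuit
#'
#' Bundles the concentration threshold `thr_o` that marks the odour as
#' present, and the change thresholds `thr_on` (a clear rise) and `thr_off`
#' (a clear drop) that gate the behavioural switch. `thr_off` must be
#' negative and `thr_on` positive.
#'
#' @param thr_o concentration threshold (a.u.).
#' @param thr_on positive change threshold (a.u. per step).
#' @param thr_off negative change threshold (a.u. per step).
#' @return a `switch_thresholds` object.
#' @examples
#' switch_thresholds(0.001, 0.02, -0.0002) # fly plume values
#' @export
switch_thresholds <- function(thr_o, thr_on, thr_off) {
  stopifnot(is.finite(thr_o), is.finite(thr_on), is.finite(thr_off))
  if (!(thr_off < 0 && 0 < thr_on)) {
    stop("thresholds must satisfy thr_off < 0 < thr_on", call. = FALSE)
  }
  structure(
    list(thr_o = thr_o, thr_on = thr_on, thr_off = thr_off),
    class = "switch_thresholds"
  )
}

#' Classify the ON/OFF/RANDOM behavioural response
#'
#' The contextual switch of the model: the sensed concentration and its
#' temporal change select which guidance strategy drives the steering
#' circuit. The mapping is the exact truth table of the switching circuit:
#'
#' | | `deltaC < thr_off` | middle | `deltaC >= thr_on` |
#' |---|---|---|---|
#' | `C < thr_o`  | RANDOM | RANDOM | ON |
#' | `C >= thr_o` | OFF    | ON     | ON |
#'
#' ON engages odour-gated anemotaxis (surge upwind), OFF engages chemotaxis
#' (recover the plume), RANDOM means no reliable sensory input: the agent
#' moves forward in a random direction.
#'
#' @param concentration sensed odour concentration (a.u.).
#' @param delta change in concentration since the previous step (a.u./step).
#' @param thresholds a [switch_thresholds()] object.
#' @return one of `"ON"`, `"OFF"`, `"RANDOM"`.
#' @export
classify_response <- function(concentration, delta, thresholds) {
  stopifnot(inherits(thresholds, "switch_thresholds"),
            is.finite(concentration), is.finite(delta))
  if (concentration < thresholds$thr_o) {
    if (delta >= thresholds$thr_on) "ON" else "RANDOM"
  } else {
    if (delta < thresholds$thr_off) "OFF" else "ON"
  }
}

#' Chemotaxis desired heading (OFF response)
#'
#' Gradient climbing from a rotationally invariant cue: when the odour
#' concentration drops, the current heading is copied and shifted by an
#' amount proportional to the drop, in a predefined turn direction; while the
#' concentration is non-decreasing the desired heading is a pure copy and the
#' agent holds course. The shift is `min(k_chemo * drop, 3)` native
#' 45-degree columns (saturating at 135 degrees), with fractional columns
#' realised at the 4.5-degree interpolated resolution and a minimum response
#' of `min_shift_cols` native columns to any sensed drop.
#'
#' The minimum matters: per-step concentration changes on the shallow flanks
#' of the study landscapes are of order `1e-3` a.u., so a purely proportional
#' (or integer-floored) shift leaves the turn response far below the
#' curvature needed to bend the path - agents settle into near-circular
#' contour orbits (proportional) or walk straight through the gradient
#' (floored) instead of climbing. Guaranteeing one 45-degree column per
#' detected drop restores the run-and-tumble regime that reaches the peak;
#' set `min_shift_cols = 0` for the pure proportional variant.
#'
#' @param current current-heading ring.
#' @param delta change in odour concentration (a.u. per step).
#' @param k_chemo chemotaxis gain (columns per a.u. of drop).
#' @param direction predefined turn direction: `"left"` (counter-clockwise,
#'   default) or `"right"`.
#' @param sign_convention `"drop"` (default; shift follows a concentration
#'   decrease, the functional reading) or `"rise"` (the literal printed
#'   alternative, shifting on an increase).
#' @param min_shift_cols minimum shift (native columns) applied to any
#'   sensed drop, however small; default 1.
#' @inheritParams copy_and_shift
#' @return desired-heading ring.
#' @export
chemotaxis_heading <- function(current, delta, k_chemo = 100,
                               direction = c("left", "right"),
                               sign_convention = c("drop", "rise"),
                               min_shift_cols = 1,
                               interp = c("fourier", "linear")) {
  direction <- match.arg(direction)
  sign_convention <- match.arg(sign_convention)
  stopifnot(k_chemo > 0, is.finite(delta), min_shift_cols >= 0)
  drive <- switch(sign_convention,
    drop = max(0, -delta),
    rise = max(0, delta)
  )
  offset_cols <- if (drive > 0) {
    min(max(k_chemo * drive, min_shift_cols), 3)
  } else {
    0
  }
  shift <- offset_cols * pi / 4 * if (direction == "left") 1 else -1
  copy_and_shift(current, shift, interp = match.arg(interp))
}

#' Anemotaxis desired heading (ON response)
#'
#' In the presence of rewarding odour the desired heading is simply the
#' upwind direction encoded by the WPN-shifted compass copy.
#'
#' @param current current-heading ring.
#' @param wind a [wpn_response()] result.
#' @inheritParams copy_and_shift
#' @return desired-heading ring decoding to the geocentric upwind direction.
#' @export
anemotaxis_heading <- function(current, wind, interp = c("fourier", "linear")) {
  upwind_ring(current, wind, interp = match.arg(interp))
}

#' Random-walk desired heading
#'
#' The RANDOM mode of the switching circuit: move forward in a random
#' direction, realised as a correlated random walk that jitters the current
#' heading uniformly within `(-jitter, +jitter)`. Uses R's RNG, so runs are
#' reproducible under a fixed seed.
#'
#' @param current_heading current heading (radians).
#' @param jitter half-width of the uniform heading perturbation (radians).
#' @param amplitude bump amplitude of the emitted ring.
#' @return desired-heading ring.
#' @export
random_heading <- function(current_heading, jitter = pi / 6, amplitude = 1) {
  stopifnot(jitter > 0, is.finite(current_heading))
  encode_heading(current_heading + stats::runif(1, -jitter, jitter), amplitude)
}
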