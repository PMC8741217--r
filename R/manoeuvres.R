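#' Working-memory desired headings for frame-of-reference transfer
#'
#' Two manoeuvres store a geocentric desired heading at a scripted trigger
#' event and later steer from it, transferring an egocentric or contextual
#' cue into the stable celestial-compass frame:
#'
#' * **Wind compensation**: at the "clutch" instant just before a gust
#'   displaces the ant, the compass bump is copied and shifted by the
#'   WPN-encoded egocentric upwind angle, so the stored heading decodes to
#'   the geocentric upwind direction - the way back toward the route after
#'   being blown downwind.
#' * **Backtracking**: when a homing ant is captured near the nest and
#'   released in unfamiliar surroundings, the compass bump is copied and
#'   shifted by a constant 180 degrees, so the stored heading points back
#'   along the pre-capture travel direction.
#'
#' The triggers themselves (clutch pose, the drop in visual novelty) are
#' experiment-script events, not sensed quantities. Once formed the memory
#' ring is immutable until cleared, and while active it is the sole desired
#' heading fed to the steering circuit; being geocentric, it is unaffected by
#' any displacement or rotation between formation and use.
#'
#' @param compass current-heading compass ring at the trigger instant.
#' @param wind a [wpn_response()] result at the trigger instant.
#' @param formed_at step index of the trigger (bookkeeping only).
#' @inheritParams copy_and_shift
#' @return a `working_memory_heading` object with fields `ring`, `active`,
#'   `formed_at`.
#' @examples
#' wm <- form_backtracking_memory(encode_heading(pi / 2))
#' decode_ring(wm$ring)$theta # -pi / 2: dash back the way it came
#' @name working_memory
NULL

new_working_memory <- function(ring, formed_at) {
  structure(
    list(ring = ring, active = TRUE, formed_at = formed_at),
    class = "working_memory_heading"
  )
}

#' @rdname working_memory
#' @export
form_wind_compensation_memory <- function(compass, wind, formed_at = NA_integer_,
                                          interp = c("fourier", "linear")) {
  ring <- copy_and_shift(compass, wind$egocentric_upwind_angle,
                         interp = match.arg(interp))
  new_working_memory(ring, formed_at)
}

#' @rdname working_memory
#' @export
form_backtracking_memory <- function(compass, formed_at = NA_integer_,
                                     interp = c("fourier", "linear")) {
  new_working_memory(copy_and_shift(compass, pi, interp = match.arg(interp)),
                     formed_at)
}

#' Steer from a working-memory desired heading
#'
#' While the memory is active it drives the steering circuit as the sole
#' desired heading, compared against the current compass bump.
#'
#' @param memory a `working_memory_heading`.
#' @param compass current-heading compass ring.
#' @inheritParams steer
#' @return a [steer()] result.
#' @export
navigate_from_memory <- function(memory, compass, k_motor = 1, offset_cols = 2) {
  stopifnot(inherits(memory, "working_memory_heading"))
  if (!isTRUE(memory$active)) {
    stop("working memory is not active: no stored desired heading to follow",
         call. = FALSE)
  }
  project_to_steering(memory$ring, compass,
                      k_motor = k_motor, offset_cols = offset_cols)
}
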