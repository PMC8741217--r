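#' Central-complex steering circuit
#'
#' Compares a desired heading against the current heading and produces a
#' signed turn command. Sixteen steering (CPU1) cells are arranged in a left
#' bank (columns 0-7) and a right bank (8-15). Each bank receives the desired
#' heading ring rolled laterally by `offset_cols` columns (counter-clockwise
#' for the left bank, clockwise for the right) as excitation, and the current
#' heading ring as inhibition; rates are rectified at zero. The turn is the
#' motor gain times the left-minus-right difference of the bank sums:
#' `turn = k_motor * (sum(left) - sum(right))`, positive counter-clockwise.
#'
#' With equal-amplitude cosine bumps the command is zero at alignment, odd in
#' the desired-minus-current offset, and (with the default two-column bank
#' projection) strictly increasing on (-90, +90) degrees, approximating a
#' `sin(offset)` steering law. A one-column projection, as in the ancestral
#' homing-circuit wiring, is available via `offset_cols = 1` but its command
#' peaks at 45 degrees and declines beyond.
#'
#' @param desired desired-heading ring (8 activations).
#' @param current current-heading ring (8 activations).
#' @param k_motor motor gain scaling activation imbalance to radians per step.
#' @param offset_cols lateral bank projection offset in native 45-degree
#'   columns (default 2).
#' @return list with `cpu1` (16 rectified steering rates, left then right)
#'   and `turn_angle` (radians per step, positive counter-clockwise).
#' @examples
#' steer(encode_heading(pi / 4), encode_heading(0))$turn_angle # turn left
#' @export
steer <- function(desired, current, k_motor = 1, offset_cols = 2) {
  assert_ring(desired, "desired")
  assert_ring(current, "current")
  stopifnot(is.finite(k_motor), offset_cols %in% 0:7)
  roll <- function(x, k) x[((seq_len(N_RING) - 1 - k) %% N_RING) + 1]
  left <- pmax(0, roll(desired, offset_cols) - current)
  right <- pmax(0, roll(desired, -offset_cols) - current)
  list(
    cpu1 = c(left, right),
    turn_angle = k_motor * (sum(left) - sum(right))
  )
}

#' Project an integrated desired heading into the steering circuit
#'
#' Duplicates the ring-attractor (or other) integrated desired-heading ring
#' into the left and right steering banks through the lateral projection
#' weights, and the compass ring into both current-heading banks, then applies
#' the steering comparison. This is the single entry point by which any
#' integrated desired heading reaches the motor command.
#'
#' @param integrated integrated desired-heading ring (8 activations).
#' @param current current-heading compass ring (8 activations).
#' @inheritParams steer
#' @return a [steer()] result.
#' @export
project_to_steering <- function(integrated, current, k_motor = 1, offset_cols = 2) {
  steer(integrated, current, k_motor = k_motor, offset_cols = offset_cols)
}
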