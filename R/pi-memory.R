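#' Path-integration memory
#'
#' Holds the home vector - the displacement from the agent to the nest in the
#' world frame - together with the reference length that normalises its ring
#' encoding. The encoded ring amplitude is `|home_vector| / reference_length`
#' clipped to `[0, 1]`, so a full-vector ant starts at amplitude 1 and the
#' path-integration cue fades to nothing as the nest is reached, which is
#' what lets odour cues take over the integrated desired heading late in the
#' route.
#'
#' @param length home-vector length (arena units, e.g. metres).
#' @param direction home-vector direction (radians, world frame).
#' @param reference_length normalising length; defaults to the initial
#'   vector length.
#' @return a `pi_memory` object.
#' @examples
#' m <- pi_memory(10, pi / 2) # full-vector ant: 10 m home vector pointing north
#' decode_ring(pi_ring(m))
#' @export
pi_memory <- function(length, direction, reference_length = length) {
  stopifnot(length >= 0, is.finite(direction), reference_length > 0)
  structure(
    list(
      home_vector = length * c(cos(direction), sin(direction)),
      reference_length = reference_length
    ),
    class = "pi_memory"
  )
}

#' Update path-integration memory with a step
#'
#' Decrements the home vector by the displacement just walked; the vector
#' always points from the agent to the nest, so walking the full vector
#' exactly zeroes the memory.
#'
#' @param memory a [pi_memory()] object.
#' @param step_vector 2-element displacement of the step just taken.
#' @return the updated `pi_memory`.
#' @export
pi_update <- function(memory, step_vector) {
  stopifnot(inherits(memory, "pi_memory"),
            length(step_vector) == 2, all(is.finite(step_vector)))
  memory$home_vector <- memory$home_vector - as.numeric(step_vector)
  memory
}

#' Ring encoding of the path-integration memory
#'
#' @param memory a [pi_memory()] object.
#' @return heading ring with amplitude `min(1, |home_vector| / reference_length)`
#'   pointing along the home vector; the zero ring when the vector vanishes.
#' @export
pi_ring <- function(memory) {
  stopifnot(inherits(memory, "pi_memory"))
  len <- sqrt(sum(memory$home_vector^2))
  if (len < 1e-12) return(rep(0, N_RING))
  amp <- min(1, len / memory$reference_length)
  encode_heading(atan2(memory$home_vector[2], memory$home_vector[1]), amp)
}

#' Ring-attractor integration of path integration with olfaction
#'
#' Combines the path-integration cue (`X1`, amplitude proportional to the
#' remaining home-vector length) with the mode-gated olfactory desired
#' heading (`X2`): the chemotaxis ring under an OFF response, the upwind
#' anemotaxis ring under an ON response, and no olfactory drive under
#' RANDOM. The olfactory cue is weighted by `k_o` times the sensed
#' concentration, so odour guidance gains influence as the plume
#' strengthens, and the two cues are settled into one desired heading by the
#' ring attractor.
#'
#' @param pi_ring path-integration heading ring (`X1`).
#' @param mode `"ON"`, `"OFF"` or `"RANDOM"` (see [classify_response()]).
#' @param chemo_ring chemotaxis desired-heading ring.
#' @param anemo_ring anemotaxis (upwind) desired-heading ring.
#' @param concentration sensed odour concentration (a.u., non-negative).
#' @param k_o olfactory weighting gain.
#' @param ra a [ring_attractor()] object.
#' @param reset passed to [ra_integrate()]; use `FALSE` to warm-start from
#'   the attractor's current state inside simulation loops.
#' @return a [ra_integrate()] result (`ring`, `attractor`, `steps`,
#'   `residual`).
#' @export
integrate_pi_olfaction <- function(pi_ring, mode, chemo_ring, anemo_ring,
                                   concentration, k_o, ra, reset = TRUE) {
  stopifnot(concentration >= 0, k_o >= 0,
            mode %in% c("ON", "OFF", "RANDOM"))
  x2 <- switch(mode,
    OFF = k_o * concentration * chemo_ring,
    ON = k_o * concentration * anemo_ring,
    RANDOM = rep(0, N_RING)
  )
  ra_integrate(ra, list(pi_ring, x2), reset = reset)
}
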