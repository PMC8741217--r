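#' Construct a ring-attractor integration network
#'
#' An eight-unit recurrent ring with a cosine excitatory kernel and a single
#' uniform-inhibition unit. Directional cues injected as heading rings are
#' integrated into one settled activity bump whose decoded direction
#' approximates the amplitude-weighted circular mean of the cues. The
#' dynamics are
#' `tau * dC/dt = -C + g(W_E2E %*% C + X + W_I2E * C_UI)`,
#' with rectifying activation `g(c) = max(0, rho + c)`, recurrent kernel
#' `W_E2E[j, i] = w0 + w1 * cos(phi_j - phi_i)`, and the uniform-inhibition
#' rate `C_UI` tracking the mean ring activation.
#'
#' The defaults put the first-harmonic recurrent gain (`4 * w1`) safely below
#' one so the settled bump amplifies, but does not distort, the input's
#' population vector: the decoded output then stays within a few degrees of
#' the weighted circular mean of the cues (see the methods vignette).
#'
#' @param w0 uniform component of the recurrent kernel.
#' @param w1 cosine component of the recurrent kernel.
#' @param w_i2e weight of the uniform-inhibition unit onto the ring.
#' @param rho activation-function offset.
#' @param tau relaxation time constant (in units of the Euler step).
#' @param dt forward-Euler step size.
#' @param tol convergence tolerance on the max per-unit change per step.
#' @param max_steps Euler step budget before signalling non-convergence.
#' @return an object of class `ring_attractor` holding the weights and the
#'   current activations (initially zero).
#' @seealso [ra_integrate()]
#' @export
ring_attractor <- function(w0 = -0.05, w1 = 0.15, w_i2e = -0.2, rho = 0,
                           tau = 1, dt = 0.2, tol = 1e-5, max_steps = 500) {
  stopifnot(tau > 0, dt > 0, tol > 0, max_steps >= 1)
  phi <- ring_angles()
  structure(
    list(
      W = outer(phi, phi, function(a, b) w0 + w1 * cos(b - a)),
      w_i2e = w_i2e, rho = rho, tau = tau, dt = dt,
      tol = tol, max_steps = max_steps,
      activations = rep(0, N_RING),
      inhibition = 0
    ),
    class = "ring_attractor"
  )
}

#' Integrate directional cues with the ring attractor
#'
#' Relaxes the ring-attractor dynamics under the summed cue input until the
#' maximum per-unit change falls below the tolerance, and returns the settled
#' ring. With a single cue the decoded output reproduces the cue direction;
#' with several cues it lies between them, pulled toward the stronger cue in
#' proportion to amplitude (approximate weighted circular mean).
#'
#' The attractor state is carried in the returned object, so passing the
#' updated attractor back in on the next call warm-starts the relaxation -
#' useful inside simulation loops where cues change slowly.
#'
#' @param ra a [ring_attractor()] object.
#' @param inputs a list of one or more heading rings (each 8 non-negative
#'   activations); they are summed into the feed-forward drive.
#' @param reset if `TRUE` (default) relax from zero activations instead of
#'   the attractor's current state.
#' @return list with `ring` (settled 8-column activity bump), `attractor`
#'   (updated state for warm starting), `steps` (Euler steps used) and
#'   `residual` (final max per-unit change).
#' @section Errors:
#' If the relaxation has not converged within `max_steps`, an error of class
#' `cxnav_ra_nonconvergence` is signalled carrying the residual; this marks
#' bad parameters rather than a recoverable condition.
#' @examples
#' ra <- ring_attractor()
#' out <- ra_integrate(ra, list(encode_heading(0), encode_heading(pi / 2)))
#' decode_ring(out$ring)$theta # ~ pi / 4
#' @export
ra_integrate <- function(ra, inputs, reset = TRUE) {
  stopifnot(inherits(ra, "ring_attractor"), is.list(inputs), length(inputs) >= 1)
  for (r in inputs) assert_ring(r, "input ring")
  X <- Reduce(`+`, inputs)
  C <- if (reset) rep(0, N_RING) else ra$activations
  coef <- ra$dt / ra$tau
  residual <- Inf
  steps <- 0L
  for (s in seq_len(ra$max_steps)) {
    drive <- as.vector(ra$W %*% C) + X + ra$w_i2e * mean(C)
    dC <- coef * (-C + pmax(0, ra$rho + drive))
    C <- C + dC
    steps <- s
    residual <- max(abs(dC))
    if (residual < ra$tol) break
  }
  if (residual >= ra$tol) {
    cnd <- structure(
      class = c("cxnav_ra_nonconvergence", "error", "condition"),
      list(
        message = sprintf(
          "ring attractor failed to converge in %d steps (residual %.3g)",
          ra$max_steps, residual
        ),
        call = sys.call(-1), residual = residual
      )
    )
    stop(cnd)
  }
  ra$activations <- C
  ra$inhibition <- mean(C)
  list(ring = C, attractor = ra, steps = steps, residual = residual)
}
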