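#' Preferred angles of the eight-column heading ring
#'
#' The compass code used throughout the model is a population of eight
#' heading cells with preferred directions spaced 45 degrees apart,
#' `phi_i = i * 45` degrees for `i = 0..7`, in the world (geocentric) frame.
#'
#' @return numeric vector of the eight preferred angles in radians.
#' @export
ring_angles <- function() (0:7) * pi / 4

N_RING <- 8L
N_FINE <- 80L

assert_ring <- function(ring, arg = "ring") {
  if (!is.numeric(ring) || length(ring) != N_RING) {
    stop(arg, " must be a numeric vector of length 8", call. = FALSE)
  }
  if (any(!is.finite(ring))) stop(arg, " contains non-finite activations", call. = FALSE)
  if (any(ring < 0)) stop(arg, " contains negative firing rates", call. = FALSE)
  invisible(ring)
}

#' Encode a direction as a cosine activity bump
#'
#' Produces the eight-column population code used for all compass, desired
#' heading and memory signals: `a_i = amplitude * (1 + cos(theta - phi_i)) / 2`.
#' A population-vector decode of the result recovers `theta` and `amplitude`.
#'
#' @param theta direction to encode, radians in the world frame.
#' @param amplitude non-negative bump amplitude (peak firing rate).
#' @return numeric vector of 8 non-negative firing rates.
#' @examples
#' encode_heading(pi / 2)
#' decode_ring(encode_heading(1.234, 0.5))
#' @export
encode_heading <- function(theta, amplitude = 1) {
  stopifnot(is.finite(theta), is.finite(amplitude))
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  amplitude * (1 + cos(theta - ring_angles())) / 2
}

#' Population-vector decode of a heading ring
#'
#' Reads out the direction and strength of a ring code as the angle and
#' (scaled) norm of the population vector
#' `(sum a_i cos(phi_i), sum a_i sin(phi_i))`. The norm is scaled so that
#' `decode_ring(encode_heading(theta, A))` returns magnitude `A`. A uniform or
#' all-zero ring has no direction: `theta` is the sentinel `NA` and the
#' magnitude is 0.
#'
#' @param ring numeric vector of 8 non-negative firing rates.
#' @return list with `theta` (radians, `NA` sentinel when undefined) and
#'   `magnitude` (same units as the activations).
#' @export
decode_ring <- function(ring) {
  assert_ring(ring)
  phi <- ring_angles()
  s <- sum(ring * sin(phi))
  c <- sum(ring * cos(phi))
  r <- sqrt(s^2 + c^2)
  mag <- 2 * r / N_RING * 2  # = r / 2 for n = 8: unit cosine bump -> 1
  if (mag < 1e-12) {
    list(theta = NA_real_, magnitude = 0)
  } else {
    list(theta = atan2(s, c), magnitude = mag)
  }
}

# trigonometric (band-limited) interpolation of a length-8 ring onto the
# 80-column fine grid; exact rotation semantics for the shift operator
upsample_fourier <- function(ring) {
  X <- stats::fft(ring)
  Y <- complex(real = rep(0, N_FINE), imaginary = rep(0, N_FINE))
  # harmonics 0..3 plus split Nyquist (harmonic 4) keep the interpolant real
  Y[1:4] <- X[1:4]
  Y[5] <- X[5] / 2
  Y[N_FINE - 3] <- X[5] / 2
  Y[(N_FINE - 2):N_FINE] <- X[6:8]
  Re(stats::fft(Y, inverse = TRUE)) / N_RING
}

upsample_linear <- function(ring) {
  # periodic piecewise-linear interpolation at the 10x finer grid
  idx <- (seq_len(N_FINE) - 1) / (N_FINE / N_RING) # fractional coarse index
  lo <- floor(idx)
  frac <- idx - lo
  a <- ring[(lo %% N_RING) + 1]
  b <- ring[((lo + 1) %% N_RING) + 1]
  a * (1 - frac) + b * frac
}

#' Copy-and-shift a heading ring
#'
#' The central operation of the model: the ring is copied and laterally
#' shifted by a sensory-determined angle, converting the current heading bump
#' into a desired heading in the same (geocentric) frame. The ring is
#' upsampled from 8 to 80 columns, rolled by the shift rounded to the
#' 4.5-degree fine resolution, and downsampled (every 10th column) back to 8.
#' Positive shifts are counter-clockwise.
#'
#' @param ring numeric vector of 8 non-negative firing rates.
#' @param shift shift angle in radians; quantised to multiples of 4.5 degrees.
#' @param interp interpolation scheme for the 8 -> 80 upsample. The default
#'   `"fourier"` (trigonometric interpolation) rotates the population vector
#'   exactly, so `decode_ring()` of the result moves by the quantised shift;
#'   `"linear"` is periodic piecewise-linear interpolation.
#' @return shifted ring, numeric vector of 8 non-negative firing rates.
#' @examples
#' r <- encode_heading(0)
#' decode_ring(copy_and_shift(r, pi / 4))$theta # one native column: 45 degrees
#' @export
copy_and_shift <- function(ring, shift, interp = c("fourier", "linear")) {
  assert_ring(ring)
  stopifnot(is.finite(shift))
  interp <- match.arg(interp)
  fine_res <- 2 * pi / N_FINE # 4.5 degrees
  s <- as.integer(round(shift / fine_res)) %% N_FINE
  up <- switch(interp,
    fourier = upsample_fourier(ring),
    linear = upsample_linear(ring)
  )
  rolled <- up[((seq_len(N_FINE) - 1 - s) %% N_FINE) + 1]
  out <- rolled[seq(1, N_FINE, by = N_FINE / N_RING)]
  pmax(out, 0) # firing rates are non-negative; clip interpolation undershoot
}
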