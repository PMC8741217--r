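#' Wrap angles to (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped into `(-pi, pi]`.
#' @examples
#' wrap_angle(3 * pi / 2)
#' @export
wrap_angle <- function(theta) {
  out <- atan2(sin(theta), cos(theta))
  # atan2 returns -pi for inputs equivalent to pi; keep the +pi representative
  out[out == -pi] <- pi
  out
}

#' Circular mean and resultant length
#'
#' Vector-sum summary of a set of directions, optionally weighted.
#'
#' @param theta numeric vector of angles (radians).
#' @param w optional non-negative weights, recycled to `length(theta)`.
#' @return a list with `mean` (radians, `NA` when the resultant vanishes) and
#'   `resultant` (mean resultant length in `[0, 1]` for unit weights).
#' @examples
#' circular_mean(c(0, pi / 2))
#' @export
circular_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  s <- sum(w * sin(theta))
  c <- sum(w * cos(theta))
  r <- sqrt(s^2 + c^2)
  list(
    mean = if (r < 1e-12) NA_real_ else atan2(s, c),
    resultant = r / sum(w)
  )
}

#' Signed angular difference a - b wrapped to (-pi, pi]
#' @param a,b angles in radians.
#' @return wrapped signed difference.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

rad2deg <- function(x) x * 180 / pi
deg2rad <- function(x) x * pi / 180

# parse an angle given either as a number (radians) or as a string using the
# pi-ratio suffix convention, e.g. "-0.5pi", "0.5 pi", "pi", "-pi"
parse_angle <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1) {
    stop("angle must be a number (radians) or a '<ratio>pi' string", call. = FALSE)
  }
  s <- gsub("\\s+", "", x)
  if (s == "pi") return(pi)
  if (s == "-pi") return(-pi)
  m <- regmatches(s, regexec("^(-?[0-9]*\\.?[0-9]+)\\*?pi$", s))[[1]]
  if (length(m) == 2) return(as.numeric(m[2]) * pi)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("cannot parse angle: ", x, call. = FALSE)
  v
}
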