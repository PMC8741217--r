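#' Analytic odour landscapes
#'
#' Two families of steady odour concentration fields drive the simulations.
#'
#' `gradient_field()` builds the windless, radially symmetric landscapes used
#' for chemotaxis. Writing `d` for the distance from the source,
#' both shapes decay as `k * exp(tau * (r/2 - d))` outside the rim circle
#' `d = r/2`; inside the rim the `"volcano"` shape dips as
#' `k * exp(tau * (d - r/2))` while the `"linear"` shape dips as
#' `k - 0.2 * exp(tau * (d - r/2))` (clamped at zero). Both attain their
#' maximum `k` exactly on the rim.
#'
#' `plume_field()` builds the steady Gaussian plume carried by a constant
#' wind of speed `u` blowing *toward* direction `theta_w`. With `dw` the
#' downwind and `cw` the crosswind distance of the query point from the
#' source, the concentration is
#' `q / (u * sigma * sqrt(2*pi)) * exp(-cw^2 / (2 * sigma^2))` with spread
#' `sigma = ks * dw`, and exactly zero on the upwind side (`cos(theta) <= 0`
#' where `theta` is the angle between the source-to-point vector and the
#' wind). Within `eps` of the source the downwind distance is clamped to
#' `eps` so the `sigma -> 0` singularity is capped at its value on the
#' eps-circle.
#'
#' @param kind `"volcano"` or `"linear"`.
#' @param k peak concentration (a.u.).
#' @param tau radial decay factor (1/cm).
#' @param r source radius (cm); the concentration peaks on the circle `r/2`.
#' @param source 2-element source position.
#' @param q emission rate (a.u. per step).
#' @param u wind speed (arena units per step).
#' @param theta_w wind direction: the direction the air flows toward
#'   (radians, world frame).
#' @param ks plume-spread tuning factor; the model admits values in
#'   `{0.5, 0.3, 0.2, 0.15, 0.1}` (smaller = tighter plume).
#' @param eps near-source guard radius (one step length by convention).
#' @return an `odour_field` object (subclass `gradient_field` or
#'   `plume_field`).
#' @examples
#' f <- gradient_field("volcano", k = 10, tau = 0.1, r = 6)
#' concentration_at(f, c(3, 0)) # on the rim: exactly k
#' @name odour_fields
NULL

#' @rdname odour_fields
#' @export
gradient_field <- function(kind = c("volcano", "linear"), k = 10, tau = 0.1,
                           r = 6, source = c(0, 0)) {
  kind <- match.arg(kind)
  stopifnot(k > 0, tau > 0, r > 0, length(source) == 2, all(is.finite(source)))
  structure(
    list(kind = kind, k = k, tau = tau, r = r, source = as.numeric(source)),
    class = c("gradient_field", "odour_field")
  )
}

#' @rdname odour_fields
#' @export
plume_field <- function(q = 10, u = 10, theta_w = -pi / 2, ks = 0.2,
                        source = c(0, 0), eps = 0.1) {
  stopifnot(
    q > 0, u > 0, is.finite(theta_w), ks > 0, eps > 0,
    length(source) == 2, all(is.finite(source))
  )
  structure(
    list(
      q = q, u = u, theta_w = theta_w, ks = ks,
      source = as.numeric(source), eps = eps
    ),
    class = c("plume_field", "odour_field")
  )
}

as_pos_matrix <- function(pos) {
  if (is.null(dim(pos))) {
    if (length(pos) != 2) stop("pos must be a 2-column position", call. = FALSE)
    pos <- matrix(pos, ncol = 2)
  }
  pos <- as.matrix(pos)
  if (ncol(pos) != 2) stop("pos must have 2 columns", call. = FALSE)
  if (any(!is.finite(pos))) stop("invalid query: non-finite position", call. = FALSE)
  pos
}

#' Query an odour field
#'
#' Evaluates the analytic concentration of a field at one or more positions.
#' Deterministic: repeated queries are bit-identical.
#'
#' @param field an `odour_field` object.
#' @param pos a 2-element position or an n-by-2 matrix/data frame of
#'   positions.
#' @return numeric vector of non-negative concentrations (a.u.).
#' @export
concentration_at <- function(field, pos) UseMethod("concentration_at")

#' @export
concentration_at.gradient_field <- function(field, pos) {
  pos <- as_pos_matrix(pos)
  d <- sqrt((pos[, 1] - field$source[1])^2 + (pos[, 2] - field$source[2])^2)
  half <- field$r / 2
  outer_branch <- field$k * exp(field$tau * (half - d))
  inner_branch <- if (field$kind == "volcano") {
    field$k * exp(field$tau * (d - half))
  } else {
    pmax(0, field$k - 0.2 * exp(field$tau * (d - half)))
  }
  ifelse(d > half, outer_branch, inner_branch)
}

#' @export
concentration_at.plume_field <- function(field, pos) {
  pos <- as_pos_matrix(pos)
  g <- plume_geometry(field, pos)
  dw <- pmax(g$downwind, field$eps)
  sigma <- field$ks * dw
  conc <- field$q / (field$u * sigma * sqrt(2 * pi)) *
    exp(-g$crosswind^2 / (2 * sigma^2))
  # upwind half-plane carries no odour; at the source sentinel (theta = 0,
  # distances 0) the capped centreline value applies
  at_source <- g$crosswind == 0 & g$downwind == 0
  ifelse(g$theta < pi / 2 | at_source, conc, 0)
}

#' Plume geometry of a query point
#'
#' Decomposes the source-to-point vector relative to the wind: `theta` is the
#' angle (in `[0, pi]`) between that vector and the wind direction, from the
#' normalised dot product with the wind vector `u * (cos(theta_w),
#' sin(theta_w))`; the crosswind distance is `dist * sin(theta)` and the
#' downwind distance `dist * cos(theta)`. A query exactly at the source
#' returns the sentinel `(theta = 0, crosswind = 0, downwind = 0)`, which
#' callers must handle.
#'
#' @param field a `plume_field`.
#' @inheritParams concentration_at
#' @return a [tibble::tibble] with columns `theta`, `crosswind`, `downwind`
#'   (one row per query position).
#' @export
plume_geometry <- function(field, pos) {
  stopifnot(inherits(field, "plume_field"))
  pos <- as_pos_matrix(pos)
  dx <- pos[, 1] - field$source[1]
  dy <- pos[, 2] - field$source[2]
  dist <- sqrt(dx^2 + dy^2)
  wx <- field$u * cos(field$theta_w)
  wy <- field$u * sin(field$theta_w)
  costh <- ifelse(
    dist == 0, 1,
    pmin(1, pmax(-1, (dx * wx + dy * wy) / (dist * field$u)))
  )
  theta <- acos(costh)
  tibble::tibble(
    theta = ifelse(dist == 0, 0, theta),
    crosswind = dist * sin(theta),
    downwind = dist * costh
  )
}

#' Sample a field with one-step concentration memory
#'
#' The agent's olfactory front end: returns the instantaneous concentration
#' and its raw temporal change against the previous sample,
#' `deltaC = C - previous`. On the first step (no previous sample) the change
#' is zero.
#'
#' @param field an `odour_field`.
#' @param pos the agent position (2-element).
#' @param previous_concentration the previous sample, or `NULL` on the first
#'   step.
#' @return list with `concentration` and `delta` (a.u. per step).
#' @export
sample_with_memory <- function(field, pos, previous_concentration = NULL) {
  conc <- concentration_at(field, pos)
  if (is.null(previous_concentration)) {
    delta <- 0
  } else {
    stopifnot(previous_concentration >= 0)
    delta <- conc - previous_concentration
  }
  list(concentration = conc, delta = delta)
}

#' Rasterise a field on a rectangular grid
#'
#' Evaluates the field on a regular grid for plotting or export.
#'
#' @param field an `odour_field`.
#' @param xlim,ylim 2-element ranges.
#' @param n number of grid points per axis.
#' @return a tibble with columns `x`, `y`, `concentration`.
#' @export
field_raster <- function(field, xlim = c(-15, 15), ylim = c(-15, 15), n = 101) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, n >= 2)
  grid <- tidyr::expand_grid(
    x = seq(xlim[1], xlim[2], length.out = n),
    y = seq(ylim[1], ylim[2], length.out = n)
  )
  grid$concentration <- concentration_at(field, cbind(grid$x, grid$y))
  grid
}
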