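# Experiment configuration: preset library, validation, YAML round trip.

# closed schema: every admissible key, with a coarse type tag
config_schema <- function() {
  list(
    name = "character", experiment = "character", kind = "character",
    k = "number", tau = "number", r = "number",
    q = "number", u = "number", w_theta = "angle", ks = "number",
    thr_o = "number", thr_on = "number", thr_off = "number",
    k_o = "number", k_chemo = "number", k_motor = "number", sl = "number",
    steps = "count", n_agents = "count", n_repeats = "count",
    seed = "count",
    start_zone = "list", odour_window = "numeric2",
    release_points = "list", release_point = "numeric2",
    pi_length = "number", pi_direction = "angle",
    capture_heading = "angle",
    distractor = "list", ra = "list",
    jitter = "angle", turn_cap = "number", offset_cols = "count",
    interp = "character", chemo_direction = "character",
    chemo_sign = "character", chemo_min_shift = "number",
    compass_amp = "number", arrival_radius = "number"
  )
}

ra_defaults <- function() {
  list(w0 = -0.05, w1 = 0.15, w_i2e = -0.2, rho = 0,
       tau = 1, dt = 0.2, tol = 1e-5, max_steps = 500)
}

common_defaults <- function() {
  list(
    seed = 1L, jitter = pi / 6, turn_cap = pi / 2, offset_cols = 2L,
    interp = "fourier", chemo_direction = "left", chemo_sign = "drop",
    chemo_min_shift = 1, compass_amp = 0.5
  )
}

#' Built-in experiment presets
#'
#' The preset library binds every parameter of the five study experiments:
#' fly chemotaxis on the volcano and linear landscapes, fly odour-gated
#' anemotaxis, the integrated fly ON/OFF experiment, ant homing with path
#' integration and the conspecific-nest distractor, and the two ant
#' manoeuvres (wind compensation, backtracking). Model parameters carry
#' their field names: `k`, `tau`, `r` (gradient landscapes), `q`, `u`,
#' `w_theta`, `ks` (plume and wind), `thr_o`/`thr_on`/`thr_off` (switching
#' thresholds), `k_o`, `k_chemo`, `k_motor` (gains) and `sl` (step length).
#'
#' @param name preset name; omit to get the full named list.
#' @return a config list (class `cx_config`), or a named list of all presets.
#' @examples
#' cx_presets("fly_chemotaxis_volcano")$sl
#' names(cx_presets())
#' @export
cx_presets <- function(name = NULL) {
  chemo <- c(common_defaults(), list(
    experiment = "chemotaxis", kind = "volcano",
    k = 10, tau = 0.1, r = 6,
    k_chemo = 100, k_motor = 1.0, sl = 0.02,
    steps = 1500L, n_agents = 5L, n_repeats = 4L,
    start_zone = list(xmin = -12, xmax = 12, ymin = -12, ymax = 12)
  ))
  anemo <- c(common_defaults(), list(
    experiment = "anemotaxis", kind = "plume",
    q = 10, u = 10, w_theta = -pi / 2, ks = 0.2,
    k_motor = 1.5, sl = 0.4,
    steps = 200L, n_agents = 4L, n_repeats = 5L,
    start_zone = list(xmin = -1.5, xmax = 1.5, ymin = -13, ymax = -5),
    odour_window = c(0.25, 0.5)
  ))
  fly_int <- utils::modifyList(anemo, list(
    experiment = "fly_integrated",
    thr_o = 0.001, thr_on = 0.02, thr_off = -2e-4,
    k_chemo = 100
  ))
  ant <- c(common_defaults(), list(
    experiment = "ant_homing", kind = "plume",
    q = 20, u = 10, w_theta = pi, ks = 0.2,
    thr_o = 1.2, thr_on = 0.5, thr_off = -2e-4,
    k_o = 0.5, k_chemo = 100, k_motor = 1.0, sl = 0.05,
    steps = 400L, n_agents = 10L,
    release_points = list(c(-1.5, -10), c(1.5, -10)),
    pi_length = 10, pi_direction = pi / 2,
    distractor = list(enabled = TRUE, x = -1.0, y = -8.0, q = 20),
    arrival_radius = 0.5,
    ra = ra_defaults()
  ))
  manoeuvre <- c(common_defaults(), list(
    kind = "plume", q = 20, u = 10, w_theta = pi, ks = 0.2,
    k_motor = 1.0, sl = 0.05,
    steps = 50L, n_agents = 10L,
    release_point = c(-1.5, -10), capture_heading = pi / 2
  ))
  presets <- list(
    fly_chemotaxis_volcano = utils::modifyList(
      chemo, list(name = "fly_chemotaxis_volcano")
    ),
    fly_chemotaxis_linear = utils::modifyList(
      chemo, list(name = "fly_chemotaxis_linear", kind = "linear")
    ),
    fly_anemotaxis = utils::modifyList(
      anemo, list(name = "fly_anemotaxis")
    ),
    fly_integrated = utils::modifyList(
      fly_int, list(name = "fly_integrated")
    ),
    ant_integrated = utils::modifyList(
      ant, list(name = "ant_integrated")
    ),
    ant_wind_compensation = utils::modifyList(
      manoeuvre, list(name = "ant_wind_compensation",
                      experiment = "wind_compensation")
    ),
    ant_backtracking = utils::modifyList(
      manoeuvre, list(name = "ant_backtracking", experiment = "backtracking")
    )
  )
  presets <- lapply(presets, function(p) structure(p, class = "cx_config"))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown preset: ", name, "; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}

#' Validate an experiment configuration
#'
#' Checks a config list against the closed schema - unknown keys are
#' rejected by name - fills shared defaults, parses pi-ratio angle strings,
#' and enforces range constraints (positive field parameters and gains,
#' `thr_off < 0 < thr_on` where thresholds apply).
#'
#' @param config a config list (e.g. from [cx_presets()] or
#'   [load_config()]).
#' @return the validated, normalised config (class `cx_config`).
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config <- utils::modifyList(common_defaults(), config)
  for (key in names(config)) {
    if (identical(schema[[key]], "angle")) {
      config[[key]] <- parse_angle(config[[key]])
    }
  }
  need <- function(keys) {
    missing <- setdiff(keys, names(config))
    if (length(missing)) {
      stop("missing configuration key(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  need(c("experiment", "kind", "sl", "k_motor", "steps", "n_agents"))
  check_pos <- function(keys) {
    for (key in intersect(keys, names(config))) {
      if (!is.numeric(config[[key]]) || config[[key]] <= 0) {
        stop("configuration key out of range (must be > 0): ", key,
             call. = FALSE)
      }
    }
  }
  check_pos(c("k", "tau", "r", "q", "u", "ks", "k_o", "k_chemo", "k_motor",
              "sl", "steps", "n_agents", "jitter", "turn_cap",
              "arrival_radius", "pi_length", "compass_amp"))
  if (config$kind %in% c("volcano", "linear")) {
    need(c("k", "tau", "r"))
  } else if (config$kind == "plume") {
    need(c("q", "u", "w_theta", "ks"))
  } else {
    stop("unknown landscape kind: ", config$kind, call. = FALSE)
  }
  if (config$experiment %in% c("fly_integrated", "ant_homing")) {
    need(c("thr_o", "thr_on", "thr_off"))
    switch_thresholds(config$thr_o, config$thr_on, config$thr_off)
  }
  if (config$experiment == "ant_homing") {
    need(c("k_o", "release_points", "pi_length", "pi_direction"))
    config$ra <- utils::modifyList(ra_defaults(),
                                   if (is.null(config$ra)) list() else config$ra)
  }
  if (config$experiment %in% c("wind_compensation", "backtracking")) {
    need(c("release_point", "capture_heading"))
  }
  if (config$experiment %in% c("chemotaxis", "anemotaxis", "fly_integrated")) {
    need(c("start_zone", "n_repeats"))
    zone <- config$start_zone
    if (!all(c("xmin", "xmax", "ymin", "ymax") %in% names(zone)) ||
        zone$xmin >= zone$xmax || zone$ymin >= zone$ymax) {
      stop("start_zone must define xmin < xmax and ymin < ymax", call. = FALSE)
    }
  }
  structure(config, class = "cx_config")
}

#' Load an experiment configuration from YAML
#'
#' A config file either names a `preset` (with optional field-level
#' overrides layered on top) or spells out a full configuration. Angles may
#' be given as numbers (radians) or as pi-ratio strings such as `"-0.5pi"`
#' or `"pi"`, which parse exactly. Unknown keys are rejected by name.
#'
#' @param path path to a YAML file.
#' @return a validated config (class `cx_config`).
#' @seealso [dump_config()] for the inverse; `load_config(dump_config(cfg))`
#'   round-trips every preset.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$preset)) {
    base <- cx_presets(raw$preset)
    raw$preset <- NULL
    # yaml represents release points / zones as plain lists; normalise below
    cfg <- utils::modifyList(base, raw)
  } else {
    cfg <- raw
  }
  if (!is.null(cfg[["release_points"]])) {
    cfg[["release_points"]] <- lapply(cfg[["release_points"]], as.numeric)
  }
  if (!is.null(cfg[["release_point"]])) {
    cfg[["release_point"]] <- as.numeric(cfg[["release_point"]])
  }
  if (!is.null(cfg[["odour_window"]])) {
    cfg[["odour_window"]] <- as.numeric(cfg[["odour_window"]])
  }
  validate_config(cfg)
}

#' Write an experiment configuration to YAML
#'
#' @param config a config list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
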