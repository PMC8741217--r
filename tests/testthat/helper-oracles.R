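# Independent oracles used across tests; deliberately written from first
# principles (plain trigonometry / brute force), not via the package's
# ring utilities.

phi8 <- (0:7) * pi / 4

# population-vector readout written out longhand
oracle_decode <- function(ring) {
  s <- sum(ring * sin(phi8))
  c <- sum(ring * cos(phi8))
  list(theta = atan2(s, c), norm = sqrt(s^2 + c^2))
}

# amplitude-weighted circular mean of two directions
oracle_two_cue_mean <- function(theta1, a1, theta2, a2) {
  atan2(a1 * sin(theta1) + a2 * sin(theta2),
        a1 * cos(theta1) + a2 * cos(theta2))
}

# wrap to (-pi, pi]
oracle_wrap <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

# Eq. 5-6 steering arithmetic evaluated directly on explicit cosine bumps
oracle_turn <- function(theta_d, theta_c, k_motor = 1, offset = 2, amp = 1) {
  bump <- function(th) amp * (1 + cos(th - phi8)) / 2
  desired <- bump(theta_d)
  current <- bump(theta_c)
  roll <- function(x, k) x[((seq_along(x) - 1 - k) %% 8) + 1]
  left <- pmax(0, roll(desired, offset) - current)
  right <- pmax(0, roll(desired, -offset) - current)
  k_motor * (sum(left) - sum(right))
}

small_chemo_config <- function(...) {
  cfg <- cx_presets("fly_chemotaxis_volcano")
  cfg$steps <- 60L
  cfg$n_agents <- 2L
  cfg$n_repeats <- 2L
  utils::modifyList(cfg, list(...))
}

small_ant_config <- function(...) {
  cfg <- cx_presets("ant_integrated")
  cfg$steps <- 40L
  cfg$n_agents <- 2L
  utils::modifyList(cfg, list(...))
}
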