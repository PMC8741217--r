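test_that("step_agent moves exactly one step length along the new heading", {
  a <- agent_state(c(0, 0), 0, sl = 0.02)
  b <- step_agent(a, 0)
  expect_equal(b$position, c(0.02, 0))
  # four quarter turns close a square
  a <- agent_state(c(1, 1), 0, sl = 1)
  for (i in 1:4) a <- step_agent(a, pi / 2)
  expect_lt(sqrt(sum((a$position - c(1, 1))^2)), 1e-9)
  # the cap clips extreme turns
  a <- agent_state(c(0, 0), 0, sl = 1)
  b <- step_agent(a, 3, turn_cap = pi / 2)
  expect_equal(b$heading, pi / 2)
})

test_that("constant-speed invariant holds for every recorded step", {
  for (traj in list(
    run_chemotaxis_experiment(small_chemo_config(), seed = 5),
    run_anemotaxis_experiment(
      utils::modifyList(cx_presets("fly_anemotaxis"),
                        list(steps = 40L, n_agents = 2L, n_repeats = 2L)),
      seed = 5
    )
  )) {
    sl <- attr(traj, "config")$sl
    steps <- traj |>
      dplyr::group_by(run, agent) |>
      dplyr::arrange(t, .by_group = TRUE) |>
      dplyr::mutate(ds = sqrt((x - dplyr::lag(x))^2 + (y - dplyr::lag(y))^2)) |>
      dplyr::filter(!is.na(ds))
    expect_equal(steps$ds, rep(sl, nrow(steps)), tolerance = 1e-12)
    expect_true(all(is.finite(traj$x)), all(is.finite(traj$y)))
  }
})

test_that("identical (config, seed) pairs give bit-identical trajectories", {
  cfg <- small_chemo_config()
  t1 <- run_chemotaxis_experiment(cfg, seed = 3)
  t2 <- run_chemotaxis_experiment(cfg, seed = 3)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- run_chemotaxis_experiment(cfg, seed = 4)
  expect_false(identical(t1$x, t3$x))
})

test_that("halving the agent count reproduces a prefix of the full run", {
  cfg <- small_chemo_config(n_agents = 4L, n_repeats = 1L)
  full <- run_chemotaxis_experiment(cfg, seed = 9)
  half <- run_chemotaxis_experiment(
    utils::modifyList(cfg, list(n_agents = 2L)), seed = 9
  )
  strip <- function(d) {
    d <- as.data.frame(d)
    attributes(d)[c("config", "seed", "experiment")] <- NULL
    d
  }
  expect_identical(strip(half),
                   strip(dplyr::filter(full, agent <= 2)))
})

test_that("a flat landscape yields straight chemotaxis trajectories", {
  # decay so small that exp() is exactly 1 in double precision everywhere
  cfg <- small_chemo_config(k = 10, tau = 1e-300, r = 6)
  traj <- run_chemotaxis_experiment(
    utils::modifyList(cfg, list(n_agents = 2L, n_repeats = 1L)), seed = 2
  )
  turns <- traj$turn[!is.na(traj$turn)]
  expect_equal(turns, rep(0, length(turns)), tolerance = 1e-9)
  # headings never change
  hd <- traj |>
    dplyr::group_by(agent) |>
    dplyr::summarise(spread = max(heading) - min(heading))
  expect_equal(hd$spread, rep(0, 2), tolerance = 1e-9)
})

test_that("agents climb the volcano to the rim concentration band", {
  traj <- run_chemotaxis_experiment(
    small_chemo_config(steps = 800L, n_agents = 3L, n_repeats = 1L,
                       start_zone = list(xmin = -6, xmax = 6,
                                         ymin = -6, ymax = 6)),
    seed = 1
  )
  final <- compute_metrics(traj)$agents$final_concentration
  expect_true(all(final > 8))
})

test_that("anemotaxis gates the odour to the second quarter of the run", {
  cfg <- utils::modifyList(cx_presets("fly_anemotaxis"),
                           list(steps = 80L, n_agents = 2L, n_repeats = 1L))
  traj <- run_anemotaxis_experiment(cfg, seed = 1)
  on_steps <- traj$t[traj$mode == "ON" & !is.na(traj$mode)]
  # mode rows are recorded at the pre-step state t, for step t+1
  expect_true(all(on_steps >= 80 / 4 & on_steps < 80 / 2))
  expect_true(all(traj$concentration[traj$t >= 80 / 2] == 0))
})

test_that("wind rotation rotates the ON-window travel direction with it", {
  base <- utils::modifyList(cx_presets("fly_anemotaxis"),
                            list(steps = 80L, n_agents = 3L, n_repeats = 1L))
  travel_dir <- function(cfg) {
    traj <- run_anemotaxis_experiment(cfg, seed = 6)
    on <- traj |>
      dplyr::filter(mode == "ON") |>
      dplyr::group_by(agent) |>
      dplyr::summarise(dx = dplyr::last(x) - dplyr::first(x),
                       dy = dplyr::last(y) - dplyr::first(y))
    atan2(sum(on$dy), sum(on$dx))
  }
  d0 <- travel_dir(base)
  rot <- utils::modifyList(base, list(w_theta = -pi / 2 + pi / 3))
  d1 <- travel_dir(rot)
  expect_lt(abs(oracle_wrap(d1 - d0 - pi / 3)), 0.2)
})

test_that("no ON response is ever logged when the odour never comes on", {
  cfg <- utils::modifyList(
    cx_presets("fly_integrated"),
    list(steps = 60L, n_agents = 2L, n_repeats = 1L,
         odour_window = c(0, 0))  # gate never opens
  )
  traj <- run_fly_integrated_experiment(cfg, seed = 2)
  expect_false(any(traj$mode == "ON", na.rm = TRUE))
  expect_true(all(traj$concentration == 0))
})

test_that("integrated flies lose and recover the plume via OFF events", {
  traj <- run_fly_integrated_experiment(cx_presets("fly_integrated"), seed = 1)
  modes <- traj$mode[!is.na(traj$mode)]
  expect_setequal(intersect(unique(modes), c("ON", "OFF", "RANDOM")),
                  c("ON", "OFF", "RANDOM"))
  # concentration recovers above the presence threshold after most losses
  thr_o <- attr(traj, "config")$thr_o
  rec <- traj |>
    dplyr::filter(!is.na(mode)) |>
    dplyr::group_by(run, agent) |>
    dplyr::summarise(
      lost = any(mode == "OFF"),
      recovered = {
        off_t <- t[mode == "OFF"]
        length(off_t) > 0 && any(t > min(off_t) & concentration > thr_o)
      },
      .groups = "drop"
    ) |>
    dplyr::filter(lost)
  expect_gt(mean(rec$recovered), 0.5)
})

test_that("ant homing integrates PI early and odour late", {
  cfg <- cx_presets("ant_integrated")
  traj <- run_ant_homing_experiment(cfg, seed = 2)
  gh <- group_heading(traj, 20)
  expect_lt(abs(oracle_wrap(gh$mean - pi / 2)), 15 * pi / 180)
  expect_gt(gh$resultant, 0.8)
  # agents reach the nest neighbourhood
  m <- compute_metrics(traj)$agents
  expect_gt(sum(!is.na(m$arrival_t)), nrow(m) / 2)
})

test_that("manoeuvre experiments concentrate headings on the stored direction", {
  for (kind in c("backtracking", "wind_compensation")) {
    preset <- if (kind == "backtracking") "ant_backtracking" else
      "ant_wind_compensation"
    traj <- run_manoeuvre_experiment(cx_presets(preset), kind, seed = 4)
    want <- attr(traj, "memory_direction")
    final <- traj |>
      dplyr::group_by(agent) |>
      dplyr::summarise(h = heading[t == max(t)])
    cm <- circular_mean(final$h)
    expect_lt(abs(oracle_wrap(cm$mean - want)), 10 * pi / 180)
    # steering concentrates an initially spread heading distribution
    init <- traj$heading[traj$t == 0]
    expect_gt(cm$resultant, circular_mean(init)$resultant)
    expect_gt(cm$resultant, 0.9)
  }
  # expected directions: backtracking stores capture + 180, wind compensation
  # stores the upwind direction theta_w + pi
  bt <- run_manoeuvre_experiment(cx_presets("ant_backtracking"),
                                 "backtracking", seed = 4)
  expect_equal(attr(bt, "memory_direction"), -pi / 2, tolerance = 1e-9)
  wc <- run_manoeuvre_experiment(cx_presets("ant_wind_compensation"),
                                 "wind_compensation", seed = 4)
  expect_lt(abs(oracle_wrap(attr(wc, "memory_direction") - 0)),
            2 * pi / 80 + 1e-9)
})

test_that("trajectory CSV export is stable and complete", {
  traj <- run_chemotaxis_experiment(small_chemo_config(), seed = 8)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(traj, f1)
  write_trajectories(run_chemotaxis_experiment(small_chemo_config(), seed = 8),
                     f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  got <- utils::read.csv(f1)
  expect_identical(names(got),
                   c("run", "agent", "t", "x", "y", "heading",
                     "concentration", "delta_c", "mode", "turn"))
})
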