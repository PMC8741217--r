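test_that("the switching truth table reproduces all six cells exactly", {
  thr <- switch_thresholds(thr_o = 1.2, thr_on = 0.5, thr_off = -2e-4)
  cells <- list(
    list(C = 0.5, d = -0.1,  want = "RANDOM"),  # low odour, clear drop
    list(C = 0.5, d = 0.0,   want = "RANDOM"),  # low odour, flat
    list(C = 0.5, d = 0.9,   want = "ON"),      # low odour, strong rise
    list(C = 2.0, d = -0.1,  want = "OFF"),     # odour present, clear drop
    list(C = 2.0, d = 0.0,   want = "ON"),      # odour present, flat
    list(C = 2.0, d = 0.9,   want = "ON")       # odour present, strong rise
  )
  for (cell in cells) {
    expect_identical(classify_response(cell$C, cell$d, thr), cell$want)
  }
})

test_that("threshold boundaries behave as closed/open per the table rows", {
  thr <- switch_thresholds(1.2, 0.5, -2e-4)
  expect_identical(classify_response(1.2, 0, thr), "ON")       # C >= thr_o row
  expect_identical(classify_response(1.2, -2e-4, thr), "ON")   # delta == thr_off
  expect_identical(classify_response(0.1, 0.5, thr), "ON")     # delta == thr_on
  expect_error(switch_thresholds(1, -0.1, -0.2), "thr_off < 0 < thr_on")
  expect_error(switch_thresholds(1, 0.1, 0.2), "thr_off < 0 < thr_on")
})

test_that("chemotaxis shift is zero for non-decreasing concentration", {
  current <- encode_heading(0.9, 1)
  for (delta in c(0, 0.001, 0.5)) {
    out <- chemotaxis_heading(current, delta)
    expect_equal(decode_ring(out)$theta, 0.9, tolerance = 1e-9)
  }
})

test_that("chemotaxis shift follows the clipped linear map of the drop", {
  current <- encode_heading(0, 1)
  k <- 100
  # drop of 1.5/k shifts 1.5 native columns = 67.5 degrees
  out <- chemotaxis_heading(current, -1.5 / k, k_chemo = k)
  expect_equal(decode_ring(out)$theta, 1.5 * pi / 4, tolerance = 1e-9)
  # arbitrarily large drops saturate at 3 columns = 135 degrees
  out <- chemotaxis_heading(current, -100, k_chemo = k)
  expect_equal(decode_ring(out)$theta, 3 * pi / 4, tolerance = 1e-9)
  # shift magnitude is monotone non-decreasing in the drop
  drops <- seq(0, 0.05, by = 0.002)
  shifts <- vapply(drops, function(d) {
    th <- decode_ring(chemotaxis_heading(current, -d, k_chemo = k))$theta
    abs(oracle_wrap(th))
  }, numeric(1))
  expect_true(all(diff(shifts) >= -1e-12))
  expect_equal(max(shifts), 3 * pi / 4, tolerance = 1e-9)
})

test_that("any sensed drop triggers at least the minimum one-column shift", {
  current <- encode_heading(0, 1)
  out <- chemotaxis_heading(current, -1e-6, k_chemo = 100)
  expect_equal(decode_ring(out)$theta, pi / 4, tolerance = 1e-9)
  # the proportional variant is recovered with min_shift_cols = 0
  out0 <- chemotaxis_heading(current, -1e-6, k_chemo = 100, min_shift_cols = 0)
  expect_equal(decode_ring(out0)$theta, 0, tolerance = 1e-9)
})

test_that("turn direction and sign convention flags work", {
  current <- encode_heading(0, 1)
  left <- chemotaxis_heading(current, -0.02, direction = "left")
  right <- chemotaxis_heading(current, -0.02, direction = "right")
  expect_gt(decode_ring(left)$theta, 0)
  expect_lt(decode_ring(right)$theta, 0)
  # literal printed alternative: shift on a rise instead of a drop
  rise <- chemotaxis_heading(current, +0.02, sign_convention = "rise")
  expect_gt(decode_ring(rise)$theta, 0)
  expect_equal(decode_ring(
    chemotaxis_heading(current, -0.02, sign_convention = "rise")
  )$theta, 0, tolerance = 1e-9)
})

test_that("anemotaxis desired heading is the upwind ring for any heading", {
  for (th in c(0, 1.1, -2.3)) {
    wind <- wpn_response(pi, th)  # ant preset: flow toward pi, upwind = 0
    ring <- anemotaxis_heading(encode_heading(th, 1), wind)
    expect_lt(abs(oracle_wrap(decode_ring(ring)$theta)), 2 * pi / 80 + 1e-9)
  }
})

test_that("random headings are reproducible and unbiased at full jitter", {
  set.seed(99)
  a <- random_heading(0.5, jitter = pi / 4)
  set.seed(99)
  b <- random_heading(0.5, jitter = pi / 4)
  expect_identical(a, b)
  # tiny jitter: essentially straight ahead
  set.seed(1)
  expect_equal(decode_ring(random_heading(0.5, jitter = 1e-9))$theta, 0.5,
               tolerance = 1e-6)
  # jitter = pi: the circular mean over many draws has negligible resultant
  set.seed(7)
  thetas <- vapply(1:10000, function(i) {
    decode_ring(random_heading(0, jitter = pi))$theta
  }, numeric(1))
  expect_lt(circular_mean(thetas)$resultant, 0.03)
})

test_that("path-integration memory tracks the home vector", {
  m <- pi_memory(10, pi / 2)
  dec <- decode_ring(pi_ring(m))
  expect_equal(dec$theta, pi / 2)
  expect_equal(dec$magnitude, 1)
  # 1 m step toward pi/2 shortens the vector to 9 m, same direction
  m2 <- pi_update(m, c(0, 1))
  expect_equal(m2$home_vector, c(0, 9))
  dec2 <- decode_ring(pi_ring(m2))
  expect_equal(dec2$theta, pi / 2)
  expect_equal(dec2$magnitude, 0.9)
  # zero step leaves the memory unchanged
  expect_identical(pi_update(m, c(0, 0))$home_vector, m$home_vector)
  # walking the full vector zeroes it
  m3 <- pi_update(m, c(0, 10))
  expect_equal(sqrt(sum(m3$home_vector^2)), 0)
  expect_identical(pi_ring(m3), rep(0, 8))
})

test_that("pi ring amplitude is clipped at one", {
  m <- pi_memory(15, 0, reference_length = 10)
  expect_equal(decode_ring(pi_ring(m))$magnitude, 1)
})

test_that("following the decoded home vector returns the agent to the nest", {
  sl <- 0.05
  m <- pi_memory(2, pi / 3)
  pos <- c(0, 0)
  nest <- 2 * c(cos(pi / 3), sin(pi / 3))
  for (i in seq_len(ceiling(2 / sl))) {
    dec <- decode_ring(pi_ring(m))
    if (is.na(dec$theta)) break
    step <- sl * c(cos(dec$theta), sin(dec$theta))
    pos <- pos + step
    m <- pi_update(m, step)
  }
  expect_lt(sqrt(sum((pos - nest)^2)), 2 * sl)
})

test_that("integration gates the olfactory cue by mode and concentration", {
  ra <- ring_attractor()
  pring <- encode_heading(pi / 2, 1)
  chemo <- encode_heading(0, 1)
  anemo <- encode_heading(pi, 1)
  # zero concentration: the olfactory term vanishes, PI wins exactly
  out <- integrate_pi_olfaction(pring, "ON", chemo, anemo, 0, 0.5, ra)
  expect_lt(abs(oracle_wrap(decode_ring(out$ring)$theta - pi / 2)), 0.02)
  # spent PI with odour present: the olfactory cue direction wins
  out <- integrate_pi_olfaction(rep(0, 8), "OFF", chemo, anemo, 2, 0.5, ra)
  expect_lt(abs(oracle_wrap(decode_ring(out$ring)$theta - 0)), 0.02)
  # ON mode routes the anemotaxis ring
  out <- integrate_pi_olfaction(rep(0, 8), "ON", chemo, anemo, 2, 0.5, ra)
  expect_lt(abs(oracle_wrap(decode_ring(out$ring)$theta - pi)), 0.02)
  # weak odour barely deflects a full PI vector
  out <- integrate_pi_olfaction(pring, "OFF", chemo, anemo, 0.1, 0.5, ra)
  expect_lt(abs(oracle_wrap(decode_ring(out$ring)$theta - pi / 2)),
            10 * pi / 180)
})

test_that("integrated direction sweeps monotonically from PI to odour cue", {
  ra <- ring_attractor()
  pring <- encode_heading(pi / 2, 1)
  chemo <- encode_heading(0, 1)
  dists <- vapply(c(0, 0.5, 1, 2, 4, 8), function(conc) {
    out <- integrate_pi_olfaction(pring, "OFF", chemo, chemo, conc, 0.5, ra)
    abs(oracle_wrap(decode_ring(out$ring)$theta - pi / 2))
  }, numeric(1))
  expect_true(all(diff(dists) > -1e-9))
  expect_lt(dists[1], 0.02)                 # pure PI
  expect_gt(dists[6], pi / 2 - 0.35)        # strong odour: near the cue
})
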