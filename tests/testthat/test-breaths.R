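test_that("square-wave flow yields one breath per cycle with exact Ti", {
  rec <- square_record(n_cycles = 5, amp = 0.5, t_on = 1, t_off = 1)
  br <- detect_breaths(rec, q_on = 0.05, t_min = 0.2)
  expect_equal(nrow(br), 5)
  expect_equal(br$ti, rep(1.0, 5))
  expect_equal(br$peep, rep(5, 5))
  # breaths tile the session: each ends where the next starts
  expect_equal(br$end_breath[-5], br$onset[-1])
  expect_true(all(br$onset < br$end_insp & br$end_insp <= br$end_breath))
})

test_that("a session without inspiration yields an empty breath table", {
  t <- seq(0, 2, by = 0.01)
  rec <- waveform_record(t, rep(5, length(t)), rep(0, length(t)))
  br <- detect_breaths(rec)
  expect_equal(nrow(br), 0)
  expect_error(detect_breaths(rec, q_on = 0), "q_on")
  expect_error(detect_breaths(rec, t_min = -1), "t_min")
})

test_that("detection count is unchanged by sub-threshold flow noise", {
  rec <- square_record(n_cycles = 6)
  n0 <- nrow(detect_breaths(rec, q_on = 0.05))
  for (s in 1:5) {
    set.seed(s)
    noisy <- rec
    noisy$flow <- rec$flow + runif(length(rec$flow), -0.024, 0.024)
    expect_equal(nrow(detect_breaths(noisy, q_on = 0.05)), n0)
  }
})

test_that("simulated sessions are segmented at the true effort onsets", {
  sim <- simulate_session(quiet_cfg(n_breaths = 30, seed = 5))
  br <- detect_breaths(sim$record)
  expect_equal(nrow(br), 30)
  true_onsets <- round(attr(sim$truth, "onset_times") / sim$record$dt) + 1
  expect_true(all(abs(br$onset - true_onsets) <= 1))
})

test_that("inspired volume integrates flow by the trapezoidal rule", {
  # rectangle: constant 0.5 L/s over 1 s is exactly 0.5 L
  t <- seq(0, 1.2, by = 0.01)
  rec <- waveform_record(t, rep(5, length(t)),
                         c(rep(0.5, 101), rep(-0.5, length(t) - 101)))
  vol <- compute_volume(rec, list(onset = 1L, end_insp = 102L))
  expect_equal(vol[1], 0)
  expect_equal(vol[101], 0.5, tolerance = 1e-12)
  # half-sine closed form: integral of sin(pi t) over [0, 1] is 2/pi
  t2 <- seq(0, 1, by = 0.001)
  rec2 <- waveform_record(t2, rep(5, length(t2)), sin(pi * t2))
  vol2 <- compute_volume(rec2, list(onset = 1L, end_insp = length(t2) + 1L))
  expect_equal(vol2[length(vol2)], 2 / pi, tolerance = 1e-5)
  expect_error(compute_volume(rec2, list(onset = 5L, end_insp = 6L)),
               "degenerate")
})

test_that("volume matches the simulator state at quadrature accuracy", {
  for (dt in c(0.01, 0.001)) {
    sim <- simulate_session(quiet_cfg(n_breaths = 3, dt = dt, seed = 9))
    br <- detect_breaths(sim$record)
    # trapezoid error bound (dt^2/12) * |dQ/dt| range; the flow slew during
    # pressurisation (ps/(t_rise*R) plus the effort term) stays below 40 L/s^2
    tol <- (dt^2 / 12) * 40
    for (b in seq_len(nrow(br))) {
      win <- br$onset[b]:(br$end_insp[b] - 1L)
      vol <- compute_volume(sim$record, br[b, ])
      expect_lt(max(abs(vol - sim$truth$v[win])), tol)
    }
  }
})

test_that("volume is non-decreasing wherever flow is non-negative", {
  sim <- simulate_session(quiet_cfg(n_breaths = 10, seed = 3))
  br <- detect_breaths(sim$record)
  for (b in seq_len(nrow(br))) {
    win <- br$onset[b]:(br$end_insp[b] - 1L)
    vol <- compute_volume(sim$record, br[b, ])
    dq <- sim$record$flow[win]
    expect_true(all(diff(vol)[dq[-length(dq)] >= 0 & dq[-1] >= 0] >= 0))
    expect_gt(max(vol), 0)
  }
})

test_that("baseline pressure is the median of the pre-onset window", {
  t <- seq(0, 2, by = 0.01)
  paw <- rep(5, length(t))
  rec <- waveform_record(t, paw, rep(0, length(t)))
  expect_equal(estimate_peep(rec, onset = 100L), 5)
  # a single spike artefact in the window does not move the median
  paw2 <- paw; paw2[98] <- 50
  rec2 <- waveform_record(t, paw2, rep(0, length(t)))
  expect_equal(estimate_peep(rec2, onset = 100L, window = 0.05), 5)
  # no pre-onset samples: falls back to the onset sample
  expect_equal(estimate_peep(rec, onset = 1L), 5)
  expect_error(estimate_peep(rec, onset = 10L, window = 0), "window")
})

test_that("configured PEEP is recovered from simulated sessions", {
  sim <- simulate_session(sim_config(n_breaths = 10, peep = 8, seed = 21))
  br <- detect_breaths(sim$record)
  expect_true(all(abs(br$peep - 8) < 0.1))
})
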