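test_that("the elastance trace is the offset-corrected pressure over volume", {
  # (15 - 5*0.5)/0.25 = 50 cmH2O/L
  tr <- compute_edrs_trace(paw = c(20, 20), flow = c(0.5, 0.5),
                           volume = c(0.25, 0.25), peep = 5)
  expect_equal(tr$edrs, c(50, 50))
  # zero volume at onset is masked, not divided
  tr2 <- compute_edrs_trace(paw = c(20, 20, 20), flow = c(0, 0.5, 0.5),
                            volume = c(0, 0.2, 0.25), peep = 5)
  expect_false(tr2$valid[1])
  expect_true(is.na(tr2$edrs[1]))
  # invalid region is a prefix
  expect_equal(which(tr2$valid), 2:3)
  expect_error(compute_edrs_trace(c(1, 2), c(0, 0), c(0, 0), 0),
               "degenerate")
  expect_error(compute_edrs_trace(c(1, 2), c(0, 0), c(0, 0.1), 0, rrs = -1),
               "rrs")
  expect_error(compute_edrs_trace(c(1, 2), c(0, 0), c(0, 0.1), 0,
                                  v_min_frac = 0.7), "v_min_frac")
})

test_that("a passive breath recovers a constant elastance", {
  cfg <- quiet_cfg(e_lung = 25, e_chest = 5, pmus_amplitude_mean = 0,
                   n_breaths = 5, seed = 1)
  sim <- simulate_session(cfg)
  fit <- edrs_fit(sim$record)
  expect_lt(max(abs(fit$edrs[fit$valid] - 30)), 0.5)
})

test_that("patient-triggered breaths start with negative elastance", {
  cfg <- quiet_cfg(pmus_amplitude_mean = 5, pmus_amplitude_cv = 0,
                   n_breaths = 10, seed = 2)
  fit <- edrs_fit(simulate_session(cfg)$record)
  first_valid <- apply(fit$edrs, 1, function(row) row[!is.na(row)][1])
  expect_true(all(first_valid < 0))
})

test_that("a larger assumed resistance shifts the trace down where flow > 0", {
  sim <- simulate_session(quiet_cfg(n_breaths = 5, seed = 4))
  rec <- sim$record
  br <- detect_breaths(rec)
  for (b in seq_len(nrow(br))) {
    win <- br$onset[b]:(br$end_insp[b] - 1L)
    vol <- compute_volume(rec, br[b, ])
    traces <- lapply(c(1, 5, 10), function(r)
      compute_edrs_trace(rec$paw[win], rec$flow[win], vol, br$peep[b],
                         rrs = r))
    pos <- rec$flow[win] > 0 & traces[[1]]$valid
    expect_true(all(traces[[1]]$edrs[pos] > traces[[2]]$edrs[pos]))
    expect_true(all(traces[[2]]$edrs[pos] > traces[[3]]$edrs[pos]))
  }
})

test_that("elastance is linear in the elastic pressure", {
  paw <- c(8, 12, 16); flow <- c(0.2, 0.4, 0.3); vol <- c(0.05, 0.2, 0.4)
  peep <- 5; a <- 3.7
  base <- compute_edrs_trace(paw, flow, vol, peep, rrs = 0.5)
  scaled <- compute_edrs_trace(peep + a * (paw - peep), flow,
                               vol, peep, rrs = a * 0.5)
  # scaling elastic pressure (paw - peep - rrs*flow) by a scales edrs by a
  expect_equal(scaled$edrs, a * base$edrs)
})

test_that("normalisation preserves constants, lines and shape", {
  m <- 73
  const <- normalize_trajectory(rep(20, m), rep(TRUE, m), ti = 0.73)
  expect_equal(const$edrs, rep(20, 101))
  expect_true(all(const$valid))
  # a linear ramp is invariant under linear interpolation
  tau_s <- (0:(m - 1)) / (m - 1)
  ramp <- normalize_trajectory(100 * tau_s, rep(TRUE, m), ti = 0.73)
  expect_equal(ramp$edrs, 100 * ramp$tau, tolerance = 1e-12)
  # two breaths sampled from the same shape of t/ti normalise identically
  for (ti in c(0.8, 1.6)) {
    mm <- round(ti / 0.01) + 1
    shape <- -40 + 90 * (0:(mm - 1)) / (mm - 1)
    tr <- normalize_trajectory(shape, rep(TRUE, mm), ti = ti)
    expect_equal(tr$edrs, -40 + 90 * tr$tau, tolerance = 1e-12)
  }
  expect_error(normalize_trajectory(1:5, c(TRUE, rep(FALSE, 4)), 1),
               "fewer than 2 valid")
  expect_error(normalize_trajectory(1:5, rep(TRUE, 5), 1, n_grid = 5),
               "n_grid")
})

test_that("grid points before the first valid sample remain invalid", {
  m <- 51
  valid <- c(rep(FALSE, 10), rep(TRUE, 41))
  tr <- normalize_trajectory(seq_len(m), valid, ti = 0.5)
  cut <- 10 / 50    # tau of the first valid sample
  expect_true(all(is.na(tr$edrs[tr$tau < cut - 1e-12])))
  expect_true(all(!is.na(tr$edrs[tr$tau >= cut])))
})

test_that("surfaces stack trajectories in acquisition order", {
  one <- constant_surface(30)
  expect_equal(nrow(one$edrs), 1)
  sim <- simulate_session(quiet_cfg(n_breaths = 30, seed = 5))
  fit <- edrs_fit(sim$record)
  expect_equal(nrow(fit$edrs), 30)
  expect_equal(fit$breath_index, 1:30)
  expect_equal(fit$breath_index, order(fit$breaths$onset))
  # inconsistent inputs are refused
  t1 <- structure(list(tau = seq(0, 1, length.out = 101), edrs = rep(1, 101),
                       valid = rep(TRUE, 101), ti = 1, breath_index = 1),
                  class = "edrs_trajectory")
  t2 <- structure(list(tau = seq(0, 1, length.out = 51), edrs = rep(1, 51),
                       valid = rep(TRUE, 51), ti = 1, breath_index = 2),
                  class = "edrs_trajectory")
  expect_error(edrs_surface(list(t1, t2), "p"), "mixed grid sizes")
  expect_error(edrs_surface(list(), "p"), "at least one")
})

test_that("the pipeline recovers the analytic elastance on both modes", {
  for (mode in c("PS", "NAVA")) {
    sim <- simulate_session(quiet_cfg(mode = mode, n_breaths = 10, seed = 6))
    expect_lt(oracle_max_error(sim), 0.5)
  }
})
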