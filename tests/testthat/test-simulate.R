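test_that("the muscular pressure profile is a non-positive half-sine", {
  expect_equal(pmus_profile(0.5, amplitude = 5, t_neural = 1), -5)
  expect_equal(pmus_profile(0, 5, 1), 0)
  expect_equal(pmus_profile(1.2, 5, 1), 0)
  expect_equal(pmus_profile(c(-0.1, 0.25, 2), 4, 1),
               c(0, -4 * sin(pi / 4), 0))
  expect_true(all(pmus_profile(seq(0, 2, 0.01), 7, 1.3) <= 0))
  expect_equal(pmus_profile(seq(0, 1, 0.1), 0, 1), rep(0, 11))
  expect_error(pmus_profile(0.1, -1, 1))
})

test_that("a seed fully determines the simulated session", {
  cfg <- sim_config(n_breaths = 8, seed = 99)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$record$paw, s2$record$paw)
  expect_identical(s1$record$flow, s2$record$flow)
  expect_identical(s1$record$eadi, s2$record$eadi)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_session(sim_config(n_breaths = 8, seed = 100))
  expect_false(identical(s1$record$paw, s3$record$paw))
})

test_that("a passive square pressure step follows the first-order response", {
  # V(t) = (ps/E)(1 - exp(-t E/R)); E = 25, R = 5, ps = 10, t = 0.2 s
  cfg <- quiet_cfg(e_lung = 20, e_chest = 5, rrs_true = 5, ps_level = 10,
                   pmus_amplitude_mean = 0, t_rise = 0, n_breaths = 2,
                   seed = 1)
  sim <- simulate_session(cfg)
  expect_equal(sim$truth$v[21], 0.4 * (1 - exp(-1)), tolerance = 1e-9)
  # recovered elastance is the configured constant. The first breath is
  # excluded: with an instant step the session opens mid-support, so it has
  # no pre-onset window from which to estimate the baseline pressure.
  fit <- edrs_fit(sim$record)
  later <- fit$breaths$onset > 1
  vals <- fit$edrs[later, , drop = FALSE][fit$valid[later, , drop = FALSE]]
  expect_lt(max(abs(vals - 25)), 0.5)
})

test_that("session bookkeeping matches the configuration", {
  sim <- simulate_session(sim_config(n_breaths = 30, resp_rate = 15,
                                     seed = 2))
  rec <- sim$record
  expect_equal(length(rec$time) * rec$dt, 120)
  expect_equal(length(attr(sim$truth, "onset_times")), 30)
  expect_true(all(is.finite(attr(sim$truth, "trigger_times"))))
  expect_true(all(diff(attr(sim$truth, "trigger_times")) > 0))
})

test_that("ground truth respects the effort-as-negative-elastance construct", {
  sim <- simulate_session(sim_config(n_breaths = 10, seed = 3))
  tr <- sim$truth
  expect_true(all(tr$p_mus <= 0))
  expect_true(all(tr$e_demand[!is.na(tr$e_demand)] <= 0))
  expect_true(all(tr$v >= 0))
  # passive limit: truth elastance is the constant passive elastance
  passive <- simulate_session(quiet_cfg(pmus_amplitude_mean = 0,
                                        n_breaths = 3, seed = 4))
  et <- passive$truth$edrs_true
  expect_equal(unique(et[!is.na(et)]), attr(passive$truth, "e_passive"))
})

test_that("emitted waveforms satisfy the generative identity exactly", {
  for (mode in c("PS", "NAVA")) {
    sim <- simulate_session(quiet_cfg(mode = mode, n_breaths = 5, seed = 5))
    cfg <- attr(sim$truth, "config")
    ok <- sim$truth$v > 0.01
    lhs <- (sim$record$paw[ok] - cfg$peep - cfg$rrs_true *
              sim$record$flow[ok]) / sim$truth$v[ok]
    expect_equal(lhs, sim$truth$edrs_true[ok], tolerance = 1e-9)
  }
})

test_that("noise is added to emitted channels only", {
  noisy <- simulate_session(sim_config(n_breaths = 3, seed = 6))
  clean <- simulate_session(quiet_cfg(n_breaths = 3, seed = 6))
  expect_identical(noisy$truth$v, clean$truth$v)
  expect_identical(noisy$truth$edrs_true, clean$truth$edrs_true)
  expect_false(identical(noisy$record$paw, clean$record$paw))
  expect_gt(stats::sd(noisy$record$paw - clean$record$paw), 0.05)
})

test_that("non-physical configurations are refused", {
  expect_error(sim_config(e_lung = -1), "e_lung")
  expect_error(sim_config(mode = "NAVA", pmus_amplitude_mean = 0), "Eadi")
  expect_error(sim_config(t_neural = 5, resp_rate = 15), "breath period")
  expect_error(sim_config(dt = 0.5), "dt")
  # suction without support drives the volume negative mid-simulation
  cfg <- quiet_cfg(ps_level = -30, pmus_amplitude_mean = 0, t_rise = 0,
                   n_breaths = 1, seed = 1)
  expect_error(simulate_session(cfg), "volume negative")
})

test_that("NAVA inherits Eadi variability while PS damps it", {
  # tidal volume CV contrast between modes (the controller mechanism)
  vt_cv <- function(mode, seed) {
    sim <- simulate_session(quiet_cfg(mode = mode, n_breaths = 40,
                                      seed = seed))
    vt <- tapply(sim$truth$v, sim$truth$breath, max)
    stats::sd(vt) / mean(vt)
  }
  expect_gt(vt_cv("NAVA", 7), 2 * vt_cv("PS", 7))
})
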