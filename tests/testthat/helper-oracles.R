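# Shared fixtures and independent oracle implementations.

# Noise-free simulation config for oracle tests.
quiet_cfg <- function(...) {
  sim_config(noise_sd_paw = 0, noise_sd_flow = 0, ...)
}

# Square-wave flow session: +amp for t_on seconds, -amp for t_off seconds,
# repeated; constant airway pressure.
square_record <- function(n_cycles = 5, amp = 0.5, t_on = 1, t_off = 1,
                          dt = 0.01, paw = 5) {
  cyc <- c(rep(amp, round(t_on / dt)), rep(-amp, round(t_off / dt)))
  flow <- rep(cyc, n_cycles)
  n <- length(flow)
  waveform_record(time = (seq_len(n) - 1) * dt, paw = rep(paw, n),
                  flow = flow, patient_id = "fix", mode = "PS")
}

# Independent empirical percentile: sort-based, linear interpolation
# between order statistics (written from the definition, not via quantile).
brute_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Max |estimated - true| elastance over all valid inspiratory samples of a
# noise-free simulated session, running the full estimation pipeline.
oracle_max_error <- function(sim, rrs = attr(sim$truth, "config")$rrs_true,
                             v_min_frac = 0.02) {
  rec <- sim$record
  br <- detect_breaths(rec)
  maxerr <- 0
  for (b in seq_len(nrow(br))) {
    row <- br[b, ]
    win <- row$onset:(row$end_insp - 1L)
    vol <- compute_volume(rec, row)
    tr <- compute_edrs_trace(rec$paw[win], rec$flow[win], vol,
                             peep = row$peep, rrs = rrs,
                             v_min_frac = v_min_frac)
    err <- abs(tr$edrs - sim$truth$edrs_true[win])[tr$valid]
    maxerr <- max(maxerr, err)
  }
  maxerr
}

# Surface built directly from constant-level trajectories (one per breath).
constant_surface <- function(levels, n_grid = 101, patient_id = "fix",
                             mode = "PS") {
  trajs <- lapply(seq_along(levels), function(i)
    structure(list(tau = seq(0, 1, length.out = n_grid),
                   edrs = rep(levels[i], n_grid),
                   valid = rep(TRUE, n_grid), ti = 1,
                   breath_index = i), class = "edrs_trajectory"))
  edrs_surface(trajs, patient_id = patient_id, mode = mode)
}
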