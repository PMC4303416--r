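# Forward simulator: spontaneous breathing on a single-compartment lung
# under PS or NAVA, with analytic ground truth for estimator validation.
#
# Within each controller phase the equation of motion
#   R dV/dt + E V = p_drive(t),  p_drive = paw - peep - p_mus
# has forcing that is a sum of (complex) exponential terms, so the volume
# is integrated exactly in closed form; the emitted waveforms are the exact
# continuous-time solution sampled on the grid. Estimator errors measured
# against this truth are therefore honest discretisation errors of the
# estimation pipeline itself.

#' Simulation configuration
#'
#' Generating parameters for one simulated ventilation session. Defaults
#' describe a moderately stiff, moderately effortful adult on partial
#' support: total passive elastance 30 cmH2O/L, resistance 5 cmH2O.s/L,
#' PEEP 5 cmH2O, 10 cmH2O of pressure support (the NAVA gain defaults to
#' the value delivering the same mean support), half-sine muscular pressure
#' of mean amplitude 5 cmH2O over a 1 s neural inspiration, 15 breaths/min.
#'
#' Breath-to-breath variability has two sources. The effort amplitude is
#' lognormal with coefficient of variation `pmus_amplitude_cv` in both
#' modes. The diaphragm electrical activity is an imperfect surrogate of
#' muscular pressure, so the emitted Eadi amplitude carries an additional
#' lognormal neuroventilatory-coupling factor with CV `coupling_cv`; PS
#' ignores Eadi, while the NAVA controller inherits this extra variability
#' through its proportional pressure delivery. The default CVs (0.25
#' effort, 0.4 coupling) reproduce the tidal-volume variability contrast
#' reported for these modes (roughly 8-10% in PS vs 25-30% in NAVA).
#'
#' @param e_lung Lung elastance, cmH2O/L. Default 20.
#' @param e_chest Chest-wall elastance, cmH2O/L. Default 10.
#' @param rrs_true True airway resistance, cmH2O.s/L. Default 5.
#' @param peep Baseline airway pressure, cmH2O. Default 5.
#' @param mode `"PS"` or `"NAVA"`.
#' @param ps_level Pressure support above PEEP, cmH2O. Default 10.
#' @param nava_gain NAVA proportional gain, cmH2O/uV. Default
#'   `ps_level / (k_eadi * pmus_amplitude_mean)`, i.e. the same mean level
#'   of support as PS.
#' @param pmus_amplitude_mean Mean peak muscular pressure, cmH2O. Default 5.
#'   0 gives a passive patient (machine-triggered in PS).
#' @param pmus_amplitude_cv Breath-to-breath CV of the effort amplitude.
#'   Default 0.25.
#' @param coupling_cv Breath-to-breath CV of the Eadi-to-pressure coupling.
#'   Default 0.4.
#' @param t_neural Neural inspiratory (effort) duration, s. Default 1.
#' @param resp_rate Respiratory rate, breaths/min. Default 15.
#' @param n_breaths Number of breaths. Default 30.
#' @param dt Sample interval, s. Default 0.01 (100 Hz).
#' @param t_rise Pressurisation rise time constant of the ventilator, s.
#'   Default 0.1 (clinical range about 0.05-0.2); 0 gives an instantaneous
#'   square step.
#' @param q_trigger Ventilator flow-trigger threshold, L/s. Default 0.05.
#' @param k_eadi Eadi per unit muscular pressure, uV/cmH2O. Default 1.
#' @param noise_sd_paw,noise_sd_flow Gaussian measurement noise SD added to
#'   the emitted pressure (cmH2O) and flow (L/s); the ground truth stays
#'   noise free. Defaults 0.1 and 0.005.
#' @param patient_id Identifier stamped on the emitted record.
#' @param seed Integer seed; the seed fully determines the session.
#' @return An object of class `edrs_sim_config` (a validated list).
#' @export
sim_config <- function(e_lung = 20, e_chest = 10, rrs_true = 5, peep = 5,
                       mode = c("PS", "NAVA"), ps_level = 10,
                       nava_gain = NULL, pmus_amplitude_mean = 5,
                       pmus_amplitude_cv = 0.25, coupling_cv = 0.4,
                       t_neural = 1, resp_rate = 15, n_breaths = 30,
                       dt = 0.01, t_rise = 0.1, q_trigger = 0.05,
                       k_eadi = 1, noise_sd_paw = 0.1,
                       noise_sd_flow = 0.005, patient_id = "sim",
                       seed = 1L) {
  mode <- match.arg(mode)
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("sim_config: ", msg)
  chk(e_lung > 0 && e_chest > 0, "e_lung and e_chest must be > 0")
  chk(rrs_true > 0, "rrs_true must be > 0")
  chk(dt > 0 && dt <= 0.1, "dt must be in (0, 0.1]")
  chk(n_breaths >= 1, "n_breaths must be >= 1")
  chk(pmus_amplitude_mean >= 0, "pmus_amplitude_mean must be >= 0")
  chk(pmus_amplitude_cv >= 0 && coupling_cv >= 0, "CVs must be >= 0")
  chk(t_neural > 0, "t_neural must be > 0")
  chk(resp_rate > 0, "resp_rate must be > 0")
  chk(t_neural < 60 / resp_rate,
      "t_neural must be shorter than the breath period")
  chk(t_rise >= 0, "t_rise must be >= 0")
  chk(q_trigger > 0, "q_trigger must be > 0")
  chk(k_eadi > 0, "k_eadi must be > 0")
  chk(noise_sd_paw >= 0 && noise_sd_flow >= 0, "noise SDs must be >= 0")
  if (mode == "NAVA")
    chk(pmus_amplitude_mean > 0, "NAVA requires patient effort (Eadi > 0)")
  if (is.null(nava_gain)) {
    nava_gain <- if (pmus_amplitude_mean > 0)
      ps_level / (k_eadi * pmus_amplitude_mean) else 0
  }
  chk(nava_gain >= 0, "nava_gain must be >= 0")
  structure(list(e_lung = e_lung, e_chest = e_chest, rrs_true = rrs_true,
                 peep = peep, mode = mode, ps_level = ps_level,
                 nava_gain = nava_gain,
                 pmus_amplitude_mean = pmus_amplitude_mean,
                 pmus_amplitude_cv = pmus_amplitude_cv,
                 coupling_cv = coupling_cv, t_neural = t_neural,
                 resp_rate = resp_rate, n_breaths = as.integer(n_breaths),
                 dt = dt, t_rise = t_rise, q_trigger = q_trigger,
                 k_eadi = k_eadi, noise_sd_paw = noise_sd_paw,
                 noise_sd_flow = noise_sd_flow,
                 patient_id = as.character(patient_id),
                 seed = as.integer(seed)),
            class = "edrs_sim_config")
}

#' @export
print.edrs_sim_config <- function(x, ...) {
  cat(sprintf("Simulated %s session: %d breaths at %g/min, dt = %g s\n",
              x$mode, x$n_breaths, x$resp_rate, x$dt))
  cat(sprintf("  E = %g + %g cmH2O/L, R = %g cmH2O.s/L, PEEP = %g cmH2O\n",
              x$e_lung, x$e_chest, x$rrs_true, x$peep))
  cat(sprintf("  effort %g cmH2O (CV %g), coupling CV %g, seed %d\n",
              x$pmus_amplitude_mean, x$pmus_amplitude_cv, x$coupling_cv,
              x$seed))
  invisible(x)
}

#' Half-sine muscular pressure profile
#'
#' Patient inspiratory effort is modelled as a non-positive half-sine of
#' pleural-side muscular pressure: `-amplitude * sin(pi * t / t_neural)`
#' for `0 <= t <= t_neural`, 0 outside. Effort lowers pressure, so the
#' profile is never positive.
#'
#' @param t Time since effort onset, s (vectorised).
#' @param amplitude Peak effort, cmH2O (>= 0).
#' @param t_neural Effort duration, s (> 0).
#' @return Muscular pressure, cmH2O (<= 0).
#' @export
#' @examples
#' pmus_profile(0.5, amplitude = 5, t_neural = 1)  # -5 at peak effort
pmus_profile <- function(t, amplitude, t_neural) {
  stopifnot(amplitude >= 0, t_neural > 0)
  ifelse(t >= 0 & t <= t_neural, -amplitude * sin(pi * t / t_neural), 0)
}

# Closed-form solution of R V' + E V = p(t) where p(t) = sum_j Re(F_j
# exp(s_j t)); returns V, Q and p on the grid `t`, continuing from (t0, V0).
.solve_phase <- function(t, t0, V0, terms, E, R) {
  lam <- E / R
  vpart <- function(tt) {
    out <- numeric(length(tt))
    for (tm in terms) out <- out + Re(tm$F * exp(tm$s * tt) / (R * (tm$s + lam)))
    out
  }
  p <- numeric(length(t))
  for (tm in terms) p <- p + Re(tm$F * exp(tm$s * t))
  V <- vpart(t) + (V0 - vpart(t0)) * exp(-lam * (t - t0))
  list(V = V, Q = (p - E * V) / R, p = p)
}

#' Simulate a spontaneous-breathing ventilation session
#'
#' Forward-simulates `n_breaths` breaths of the single-compartment
#' equation of motion `paw = peep + rrs*Q + E*V + p_mus` under the
#' configured controller and returns the emitted waveforms together with
#' the analytic ground truth. Each breath: the patient effort starts at
#' the breath boundary and drives flow through the trigger threshold; the
#' ventilator then pressurises (PS: constant support with an exponential
#' rise; NAVA: gain times the emitted Eadi), holds until the neural time
#' ends, and expiration is passive exponential decay against PEEP. A
#' passive PS configuration (`pmus_amplitude_mean = 0`) is
#' machine-triggered at the breath boundary. Measurement noise is added to
#' the emitted pressure and flow only.
#'
#' @param config An [sim_config()].
#' @return A list with components `record` (a [waveform_record()] with
#'   Eadi channel) and `truth`, a data frame of class `edrs_sim_truth`
#'   with per-sample `time`, `breath`, `p_mus` (cmH2O, <= 0), `v` (L,
#'   noise-free), `edrs_true` and `e_demand` (cmH2O/L, `NA` where `v = 0`),
#'   plus attributes `config`, `e_passive` (= `e_lung + e_chest`),
#'   `onset_times` (effort onsets, s), `trigger_times` (support onsets, s;
#'   `NA` for unsupported breaths), `amplitudes` and `couplings`
#'   (per-breath draws).
#' @export
#' @examples
#' sim <- simulate_session(sim_config(n_breaths = 5, seed = 42))
#' sim$record
#' head(sim$truth)
simulate_session <- function(config) {
  stopifnot(inherits(config, "edrs_sim_config"))
  cf <- config
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(cf$seed)
  E <- cf$e_lung + cf$e_chest; R <- cf$rrs_true
  dt <- cf$dt; tn <- cf$t_neural
  mu <- if (cf$t_rise > 0) 1 / cf$t_rise else Inf
  lam <- E / R
  if (is.finite(mu) && abs(lam - mu) < 1e-6) mu <- mu * (1 + 1e-6)
  om <- pi / tn
  nb_samp <- round(60 / cf$resp_rate / dt)
  n <- cf$n_breaths * nb_samp
  draw <- function(m, cv) {
    if (m == 0) return(rep(0, cf$n_breaths))
    if (cv <= 0) return(rep(m, cf$n_breaths))
    sdl <- sqrt(log(1 + cv^2))
    rlnorm(cf$n_breaths, meanlog = log(m) - sdl^2 / 2, sdlog = sdl)
  }
  a_i <- draw(cf$pmus_amplitude_mean, cf$pmus_amplitude_cv)
  c_i <- draw(1, cf$coupling_cv)
  paw_v <- numeric(n); flow <- numeric(n); eadi <- numeric(n)
  pmus <- numeric(n); vol <- numeric(n)
  trig_times <- rep(NA_real_, cf$n_breaths)
  sin_term <- function(A) list(list(F = -1i * A, s = 1i * om))
  tt <- (seq_len(nb_samp) - 1L) * dt          # local breath time
  i_eff <- which(tt <= tn + 1e-12)            # effort window
  for (b in seq_len(cf$n_breaths)) {
    k0 <- (b - 1L) * nb_samp
    a <- a_i[b]; cc <- c_i[b]
    Vloc <- numeric(nb_samp); Qloc <- numeric(nb_samp); pv <- numeric(nb_samp)
    # phase 1: effort against PEEP alone, from V = 0
    s1 <- .solve_phase(tt[i_eff], 0, 0, sin_term(a), E, R)
    kt <- which(s1$Q >= cf$q_trigger)[1L]
    if (is.na(kt) && a == 0 && cf$mode == "PS") kt <- 1L   # machine trigger
    if (!is.na(kt)) {
      trig_times[b] <- (k0 + kt - 1L) * dt
      i2 <- i_eff[i_eff >= kt]
      tkt <- tt[kt]
      if (cf$mode == "PS") {
        terms2 <- c(sin_term(a), list(list(F = cf$ps_level + 0i, s = 0 + 0i)))
        if (is.finite(mu))
          terms2 <- c(terms2, list(list(F = -cf$ps_level * exp(mu * tkt) + 0i,
                                        s = -mu + 0i)))
      } else {
        gk <- cf$nava_gain * cf$k_eadi * cc
        terms2 <- sin_term((1 + gk) * a)
        if (is.finite(mu))
          terms2 <- c(terms2, list(list(F = 1i * gk * a * exp(mu * tkt),
                                        s = 1i * om - mu)))
      }
      s2 <- .solve_phase(tt[i2], tkt, s1$V[kt], terms2, E, R)
      pre <- seq_len(kt - 1L)
      if (length(pre)) { Vloc[pre] <- s1$V[pre]; Qloc[pre] <- s1$Q[pre] }
      Vloc[i2] <- s2$V; Qloc[i2] <- s2$Q
      pv[i2] <- s2$p - a * sin(om * tt[i2])   # ventilator pressure component
      klast <- i2[length(i2)]
    } else {
      # unsupported effort breath: threshold never reached
      Vloc[i_eff] <- s1$V; Qloc[i_eff] <- s1$Q
      klast <- i_eff[length(i_eff)]
    }
    # phase 3: passive expiration against PEEP
    if (klast < nb_samp) {
      i3 <- (klast + 1L):nb_samp
      s3 <- .solve_phase(tt[i3], tt[klast], Vloc[klast], list(), E, R)
      Vloc[i3] <- s3$V; Qloc[i3] <- s3$Q
    }
    if (any(Vloc < -1e-9)) {
      k_bad <- which(Vloc < -1e-9)[1L]
      stop("simulate_session: non-physical configuration drives volume ",
           "negative at step ", k0 + k_bad, " (breath ", b, ")")
    }
    ks <- k0 + seq_len(nb_samp)
    pm <- pmus_profile(tt, a, tn)
    vol[ks] <- Vloc; flow[ks] <- Qloc; pmus[ks] <- pm
    paw_v[ks] <- pv
    eadi[ks] <- cf$k_eadi * cc * (-pm)
  }
  time <- (seq_len(n) - 1L) * dt
  paw <- cf$peep + paw_v
  paw_out <- if (cf$noise_sd_paw > 0) paw + rnorm(n, 0, cf$noise_sd_paw)
             else paw
  flow_out <- if (cf$noise_sd_flow > 0) flow + rnorm(n, 0, cf$noise_sd_flow)
              else flow
  record <- waveform_record(time, paw_out, flow_out, eadi,
                            patient_id = cf$patient_id, mode = cf$mode)
  truth <- data.frame(time = time,
                      breath = rep(seq_len(cf$n_breaths), each = nb_samp),
                      p_mus = pmus, v = vol,
                      edrs_true = ifelse(vol > 0, E + pmus / vol, NA_real_),
                      e_demand = ifelse(vol > 0, pmus / vol, NA_real_))
  class(truth) <- c("edrs_sim_truth", "data.frame")
  attr(truth, "config") <- cf
  attr(truth, "e_passive") <- E
  attr(truth, "onset_times") <- (seq_len(cf$n_breaths) - 1L) * nb_samp * dt
  attr(truth, "trigger_times") <- trig_times
  attr(truth, "amplitudes") <- a_i
  attr(truth, "couplings") <- c_i
  list(record = record, truth = truth)
}
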