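# Core elastance estimation: per-sample Edrs trace (single-compartment
# model with fixed airway resistance), normalisation onto a common
# inspiratory-time grid, per-session surfaces, and the edrs_fit()
# user-facing fitting function.

#' Per-sample time-varying elastance of one breath
#'
#' Computes `edrs[k] = (paw[k] - peep - rrs * flow[k]) / volume[k]` over an
#' inspiratory window. The airway resistance `rrs` is an assumed constant:
#' it is not identifiable per-sample from pressure and flow alone, and
#' holding it fixed makes trajectories directly comparable across modes
#' within a patient. Samples whose volume is below `v_min_frac` of the
#' breath's tidal volume are masked invalid: the ratio is numerically
#' meaningless as volume approaches zero at onset, while small-but-nonzero
#' volumes still carry the genuinely negative elastance produced by patient
#' effort. The masked region is always a prefix of the breath.
#'
#' @param paw Airway pressure over the window, cmH2O.
#' @param flow Flow over the window, L/s.
#' @param volume Inspired volume from [compute_volume()], L.
#' @param peep Baseline pressure to subtract, cmH2O.
#' @param rrs Assumed airway resistance, cmH2O.s/L (> 0). Default 5.
#' @param v_min_frac Volume mask threshold as a fraction of tidal volume,
#'   in (0, 0.5). Default 0.02.
#' @return A list with `edrs` (cmH2O/L, `NA` where masked) and logical
#'   `valid`.
#' @export
#' @examples
#' # direct substitution: (15 - 5*0.5) / 0.25 = 50 cmH2O/L
#' compute_edrs_trace(paw = c(20, 20), flow = c(0.5, 0.5),
#'                    volume = c(0.25, 0.25), peep = 5)$edrs
compute_edrs_trace <- function(paw, flow, volume, peep, rrs = 5,
                               v_min_frac = 0.02) {
  if (!is.numeric(rrs) || rrs <= 0)
    stop("compute_edrs_trace: rrs must be > 0")
  if (!is.numeric(v_min_frac) || v_min_frac <= 0 || v_min_frac >= 0.5)
    stop("compute_edrs_trace: v_min_frac must be in (0, 0.5)")
  m <- length(volume)
  if (length(paw) != m || length(flow) != m)
    stop("compute_edrs_trace: channel lengths differ")
  vt <- max(volume)
  if (!is.finite(vt) || vt <= 0)
    stop("compute_edrs_trace: degenerate breath, no inspired volume")
  first <- which(volume >= v_min_frac * vt & volume > 0)[1L]
  if (is.na(first))
    stop("compute_edrs_trace: degenerate breath, all samples masked")
  valid <- seq_len(m) >= first
  edrs <- rep(NA_real_, m)
  edrs[valid] <- (paw[valid] - peep - rrs * flow[valid]) / volume[valid]
  list(edrs = edrs, valid = valid)
}

#' Normalise an elastance trace onto the common inspiratory-time grid
#'
#' Inspiratory time differs breath to breath, so trajectories are compared
#' on normalised inspiratory time tau in \[0, 1\] (0-100% of inspiration).
#' Sample times are mapped linearly onto \[0, 1\] and the valid portion of
#' the trace is linearly interpolated onto a uniform grid of `n_grid`
#' points; grid points earlier than the first valid sample remain invalid.
#'
#' @param edrs Per-sample elastance from [compute_edrs_trace()], cmH2O/L.
#' @param valid Logical mask from [compute_edrs_trace()].
#' @param ti Inspiratory time of the breath, s.
#' @param n_grid Number of grid points (>= 10). Default 101, i.e. one node
#'   per percent of inspiration.
#' @param breath_index Ordinal of the breath within its session.
#' @return An object of class `edrs_trajectory`: list with `tau`, `edrs`
#'   (`NA` where invalid), `valid`, `ti`, `breath_index`.
#' @export
normalize_trajectory <- function(edrs, valid, ti, n_grid = 101L,
                                 breath_index = NA_integer_) {
  if (!is.numeric(n_grid) || n_grid < 10L)
    stop("normalize_trajectory: n_grid must be >= 10")
  m <- length(edrs)
  if (length(valid) != m)
    stop("normalize_trajectory: edrs and valid lengths differ")
  if (sum(valid) < 2L)
    stop("normalize_trajectory: degenerate breath, fewer than 2 valid samples")
  tau_s <- (seq_len(m) - 1L) / (m - 1L)
  grid <- seq(0, 1, length.out = n_grid)
  ok <- grid >= tau_s[valid][1L] - 1e-12
  out <- rep(NA_real_, n_grid)
  out[ok] <- approx(tau_s[valid], edrs[valid], xout = grid[ok],
                    method = "linear", rule = 2, ties = "ordered")$y
  structure(list(tau = grid, edrs = out, valid = ok & !is.na(out),
                 ti = ti, breath_index = breath_index),
            class = "edrs_trajectory")
}

#' Assemble an elastance surface from per-breath trajectories
#'
#' Stacks normalised trajectories in acquisition order into the
#' breath-by-tau surface ("Edrs mapping") for one patient and mode. The
#' surface is the unit that percentile summaries, AUC metrics and mode
#' comparisons operate on.
#'
#' @param trajectories List of [normalize_trajectory()] results sharing the
#'   same grid size.
#' @param patient_id Patient identifier.
#' @param mode Ventilation mode, `"PS"` or `"NAVA"`.
#' @param params Optional list of estimation parameters to carry along.
#' @return An object of class `edrs_surface`: list with `patient_id`,
#'   `mode`, `tau`, matrices `edrs` and `valid` (breaths x grid), `ti`,
#'   `breath_index`, `params`.
#' @export
edrs_surface <- function(trajectories, patient_id, mode = c("PS", "NAVA"),
                         params = list()) {
  mode <- match.arg(mode)
  if (!is.list(trajectories) || length(trajectories) == 0L)
    stop("edrs_surface: need at least one trajectory")
  if (!all(vapply(trajectories, inherits, logical(1), "edrs_trajectory")))
    stop("edrs_surface: inputs must be edrs_trajectory objects")
  sizes <- vapply(trajectories, function(tr) length(tr$tau), integer(1))
  if (length(unique(sizes)) != 1L)
    stop("edrs_surface: mixed grid sizes: ",
         paste(unique(sizes), collapse = ", "))
  idx <- vapply(trajectories, function(tr) tr$breath_index, numeric(1))
  if (anyNA(idx)) idx <- seq_along(trajectories)
  structure(list(
    patient_id = as.character(patient_id), mode = mode,
    tau = trajectories[[1L]]$tau,
    edrs = unname(do.call(rbind, lapply(trajectories, `[[`, "edrs"))),
    valid = unname(do.call(rbind, lapply(trajectories, `[[`, "valid"))),
    ti = unname(vapply(trajectories, function(tr) tr$ti, numeric(1))),
    breath_index = as.integer(idx), params = params),
    class = "edrs_surface")
}

#' Fit the time-varying elastance model to a ventilation session
#'
#' The main fitting function. Segments the session into breaths, integrates
#' inspired volume, removes the per-breath baseline pressure, evaluates the
#' per-sample elastance \eqn{E_{drs}(t) = (P_{aw} - PEEP - R_{rs} Q)/V}
#' with the assumed constant airway resistance, and normalises each
#' breath's trajectory onto the common inspiratory-time grid. Breaths whose
#' trace degenerates (no inspired volume, or fewer than two valid samples)
#' are dropped with a warning.
#'
#' @param record A [waveform_record()].
#' @param rrs Assumed airway resistance, cmH2O.s/L. Default 5, a realistic
#'   physiological value for intubated patients; see
#'   [compute_edrs_trace()] for why it is held constant.
#' @param n_grid Normalised-time grid size. Default 101.
#' @param v_min_frac Early-volume mask threshold. Default 0.02.
#' @param q_on,t_min,peep_window Segmentation parameters, see
#'   [detect_breaths()].
#' @return An object of class `c("edrs_fit", "edrs_surface")`; additionally
#'   carries `breaths` (the segmentation table), `record`, `n_dropped` and
#'   `call`. Methods: [print()], [summary.edrs_surface()],
#'   [coef.edrs_surface()], [plot.edrs_surface()],
#'   [residuals.edrs_fit()].
#' @export
#' @examples
#' sim <- simulate_session(sim_config(n_breaths = 12, seed = 7))
#' fit <- edrs_fit(sim$record)
#' fit
#' summary(fit)
edrs_fit <- function(record, rrs = 5, n_grid = 101L, v_min_frac = 0.02,
                     q_on = 0.05, t_min = 0.2, peep_window = 0.05) {
  stopifnot(inherits(record, "waveform_record"))
  breaths <- detect_breaths(record, q_on = q_on, t_min = t_min,
                            peep_window = peep_window)
  if (nrow(breaths) == 0L)
    stop("edrs_fit: no breaths detected in session '", record$patient_id, "'")
  trajs <- vector("list", nrow(breaths)); dropped <- 0L
  for (b in seq_len(nrow(breaths))) {
    br <- breaths[b, ]
    tr <- tryCatch({
      win <- br$onset:(br$end_insp - 1L)
      vol <- compute_volume(record, br)
      trace <- compute_edrs_trace(record$paw[win], record$flow[win], vol,
                                  peep = br$peep, rrs = rrs,
                                  v_min_frac = v_min_frac)
      normalize_trajectory(trace$edrs, trace$valid, ti = br$ti,
                           n_grid = n_grid, breath_index = br$index)
    }, error = function(e) e)
    if (inherits(tr, "error")) dropped <- dropped + 1L else trajs[[b]] <- tr
  }
  trajs <- trajs[!vapply(trajs, is.null, logical(1))]
  if (dropped > 0L)
    warning("edrs_fit: dropped ", dropped, " degenerate breath(s)")
  if (!length(trajs))
    stop("edrs_fit: all detected breaths were degenerate")
  fit <- edrs_surface(trajs, patient_id = record$patient_id,
                      mode = record$mode,
                      params = list(rrs = rrs, n_grid = as.integer(n_grid),
                                    v_min_frac = v_min_frac, q_on = q_on,
                                    t_min = t_min,
                                    peep_window = peep_window))
  fit$breaths <- breaths
  fit$record <- record
  fit$n_dropped <- dropped
  fit$call <- match.call()
  class(fit) <- c("edrs_fit", class(fit))
  fit
}
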