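# Breath segmentation from the flow waveform, inspired volume, baseline
# pressure. Only the inspiratory limb is analysed downstream; expiration is
# retained solely to delimit breaths.

#' Detect breaths in a ventilation session
#'
#' Partitions a session into breaths using the flow waveform. A breath is
#' triggered where flow rises through `+q_on` and remains non-negative for
#' at least `t_min`; the onset is then back-tracked to the start of the
#' surrounding positive-flow run (including a leading zero-flow sample), so
#' that the inspired-volume integral starts where flow actually departs
#' from zero rather than at the threshold crossing. Inspiration ends at the
#' first sample where flow falls below zero; the breath ends at the next
#' onset (or the end of the session). Candidate breaths with an inspiratory
#' time shorter than `t_min` are discarded.
#'
#' @param record A [waveform_record()].
#' @param q_on Flow trigger threshold, L/s (> 0). Default 0.05.
#' @param t_min Minimum inspiratory duration, s (> 0). Default 0.2.
#' @param peep_window Window before onset over which baseline pressure is
#'   estimated, s. Default 0.05. See [estimate_peep()].
#' @return A data frame of class `edrs_breaths` with one row per breath:
#'   `index`, `onset`, `end_insp`, `end_breath` (sample indices; the end
#'   indices are exclusive), `ti` (inspiratory time, s) and `peep`
#'   (baseline airway pressure, cmH2O). Zero rows when no breath is found.
#' @export
#' @examples
#' sim <- simulate_session(sim_config(n_breaths = 3, seed = 1))
#' detect_breaths(sim$record)
detect_breaths <- function(record, q_on = 0.05, t_min = 0.2,
                           peep_window = 0.05) {
  stopifnot(inherits(record, "waveform_record"))
  if (!is.numeric(q_on) || q_on <= 0)
    stop("detect_breaths: q_on must be > 0")
  if (!is.numeric(t_min) || t_min <= 0)
    stop("detect_breaths: t_min must be > 0")
  flow <- record$flow; dt <- record$dt; n <- length(flow)
  crossings <- which(flow[-1L] >= q_on & flow[-n] < q_on) + 1L
  if (flow[1L] >= q_on) crossings <- c(1L, crossings)  # session starts mid-rise
  neg_idx <- which(flow < 0)                   # sorted
  onset <- integer(0); end_insp <- integer(0)
  last_end <- 0L
  for (k in crossings) {
    if (k <= last_end) next                    # inside the previous breath
    # first negative-flow sample at or after k (binary search)
    pos <- findInterval(k - 0.5, neg_idx) + 1L
    ei <- if (pos <= length(neg_idx)) neg_idx[pos] else n + 1L  # exclusive
    if ((ei - k) * dt < t_min) { last_end <- ei - 1L; next }  # not sustained
    z <- k
    while (z > 1L && flow[z - 1L] > 0) z <- z - 1L
    on <- if (z > 1L && abs(flow[z - 1L]) <= 1e-9) z - 1L else z
    last_end <- ei - 1L
    if ((ei - on) * dt < t_min) next
    onset <- c(onset, on); end_insp <- c(end_insp, ei)
  }
  nb <- length(onset)
  peep <- vapply(onset, function(on) estimate_peep(record, on, peep_window),
                 numeric(1))
  out <- data.frame(index = seq_len(nb), onset = onset, end_insp = end_insp,
                    end_breath = if (nb) c(onset[-1L], n + 1L) else integer(0),
                    ti = (end_insp - onset) * dt, peep = peep)
  class(out) <- c("edrs_breaths", "data.frame")
  out
}

#' Inspired volume of one breath
#'
#' Cumulative trapezoidal integral of flow over the inspiratory window
#' `[onset, end_insp)`, reset to zero at onset. Per-breath resetting
#' eliminates integrator drift across breaths, which matters because the
#' elastance estimate divides by within-breath inspired volume.
#'
#' @param record A [waveform_record()].
#' @param breath One row of the data frame returned by [detect_breaths()]
#'   (or any list with `onset` and `end_insp` sample indices).
#' @return Numeric vector of volumes (litres), one per inspiratory sample,
#'   starting at 0.
#' @export
compute_volume <- function(record, breath) {
  stopifnot(inherits(record, "waveform_record"))
  on <- breath$onset[1L]; ei <- breath$end_insp[1L]
  n <- length(record$flow)
  if (is.na(on) || is.na(ei) || on < 1L || ei > n + 1L || ei - on < 2L)
    stop("compute_volume: degenerate inspiratory window [", on, ", ", ei, ")")
  q <- record$flow[on:(ei - 1L)]
  m <- length(q)
  c(0, cumsum((q[-1L] + q[-m]) / 2 * record$dt))
}

#' Baseline (offset) airway pressure before a breath
#'
#' The elastance model is defined on pressure above baseline, so the
#' per-breath offset must be removed before estimation. The estimate is the
#' median of airway pressure over the `window` seconds immediately before
#' onset (median, so a single spike artefact does not corrupt it), clipped
#' to the session start; if there are no pre-onset samples the pressure at
#' onset is used.
#'
#' @param record A [waveform_record()].
#' @param onset Onset sample index of the breath.
#' @param window Look-back window, s (> 0). Default 0.05.
#' @return Baseline pressure, cmH2O.
#' @export
estimate_peep <- function(record, onset, window = 0.05) {
  stopifnot(inherits(record, "waveform_record"))
  if (!is.numeric(window) || window <= 0)
    stop("estimate_peep: window must be > 0")
  onset <- as.integer(onset[1L])
  if (onset <= 1L) return(record$paw[max(onset, 1L)])
  from <- max(1L, onset - max(1L, round(window / record$dt)))
  median(record$paw[from:(onset - 1L)])
}
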