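# Percentile trajectory summaries, the AUC elastance metric and the
# severity flag.

#' Pointwise percentile trajectories of an elastance surface
#'
#' At each normalised-time grid point, computes the requested percentiles
#' of elastance across all breaths that are valid at that point (empirical
#' percentile with linear interpolation between order statistics, the
#' default quantile definition in R). Percentiles are pointwise across
#' breaths, not rankings of whole breaths: this is the only construction
#' that yields one smooth curve per level across the whole inspiration. A
#' grid point with fewer than two valid breaths is invalid in the output.
#'
#' @param surface An [edrs_surface()] (or [edrs_fit()]).
#' @param levels Percentile levels in percent, default `c(5, 25, 50, 75, 95)`.
#' @return An object of class `edrs_percentiles`: list with `levels`,
#'   `tau`, matrix `traj` (levels x grid, `NA` where invalid), logical
#'   `valid` per grid point, and `n_breaths`.
#' @export
percentile_trajectories <- function(surface, levels = c(5, 25, 50, 75, 95)) {
  stopifnot(inherits(surface, "edrs_surface"))
  if (is.null(surface$edrs) || nrow(surface$edrs) == 0L)
    stop("percentile_trajectories: empty surface")
  if (any(levels < 0 | levels > 100))
    stop("percentile_trajectories: levels must be percentages in [0, 100]")
  g <- length(surface$tau)
  traj <- matrix(NA_real_, nrow = length(levels), ncol = g,
                 dimnames = list(paste0("p", levels), NULL))
  for (j in seq_len(g)) {
    vals <- surface$edrs[surface$valid[, j], j]
    vals <- vals[is.finite(vals)]
    if (length(vals) >= 2L)
      traj[, j] <- quantile(vals, probs = levels / 100, names = FALSE,
                            type = 7)
  }
  structure(list(levels = levels, tau = surface$tau, traj = traj,
                 valid = !is.na(traj[1L, ]), n_breaths = nrow(surface$edrs)),
            class = "edrs_percentiles")
}

#' Area under an elastance trajectory
#'
#' Integrates a trajectory over a window of normalised inspiratory time
#' (default \[0.3, 1.0\], skipping the effort-dominated early portion) by
#' exact integration of the piecewise-linear interpolant, i.e. the
#' trapezoidal rule with interpolated window endpoints. The normalised
#' axis carries nominal units of seconds, so a constant elastance E yields
#' `0.7 * E` and the result is in cmH2O.s/L.
#'
#' @param edrs An `edrs_trajectory`, or a numeric vector of elastance
#'   values on the grid `tau`.
#' @param tau Grid of normalised times; taken from the trajectory object
#'   when `edrs` is one.
#' @param window Integration window on the tau axis. Default `c(0.3, 1)`.
#' @return AUC in cmH2O.s/L.
#' @export
#' @examples
#' tau <- seq(0, 1, length.out = 101)
#' auc_edrs(rep(40, 101), tau)       # 0.7 * 40 = 28
#' auc_edrs(100 * tau, tau)          # (1 - 0.09)/2 * 100 = 45.5
auc_edrs <- function(edrs, tau = NULL, window = c(0.3, 1)) {
  if (inherits(edrs, "edrs_trajectory")) {
    tau <- edrs$tau
    edrs <- edrs$edrs
  }
  if (is.null(tau) || length(tau) != length(edrs))
    stop("auc_edrs: need a tau grid matching the trajectory")
  if (length(window) != 2L || window[1L] >= window[2L] ||
      window[1L] < min(tau) - 1e-12 || window[2L] > max(tau) + 1e-12)
    stop("auc_edrs: invalid integration window")
  inside <- tau > window[1L] & tau < window[2L]
  step <- if (length(tau) > 1L) max(diff(tau)) else 0
  if (anyNA(edrs[tau >= window[1L] - step - 1e-12 &
                   tau <= window[2L] + 1e-12]))
    stop("auc_edrs: trajectory has invalid grid points inside the window [",
         window[1L], ", ", window[2L], "]")
  ends <- approx(tau, edrs, xout = window, method = "linear",
                 ties = "ordered")$y
  x <- c(window[1L], tau[inside], window[2L])
  y <- c(ends[1L], edrs[inside], ends[2L])
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' ARDS-like stiffness flag
#'
#' Elevated respiratory system elastance (>= 25 cmH2O/L) is characteristic
#' of ARDS; an AUC elastance at or above 25 cmH2O.s/L over the normalised
#' window therefore flags ARDS-like stiffness. The threshold is inclusive.
#'
#' @param auc AUC elastance value(s), cmH2O.s/L.
#' @return Logical, `TRUE` where `auc >= 25`.
#' @export
severity_flag <- function(auc) {
  if (any(!is.finite(auc)))
    stop("severity_flag: auc must be finite")
  auc >= 25
}
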