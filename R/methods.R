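# S3 methods for fitted elastance surfaces.

#' @export
print.edrs_surface <- function(x, ...) {
  cat("Time-varying elastance surface\n")
  cat(sprintf("  patient: %s   mode: %s\n", x$patient_id, x$mode))
  cat(sprintf("  %d breaths on a %d-point normalised-time grid\n",
              nrow(x$edrs), length(x$tau)))
  if (!is.null(x$params$rrs))
    cat(sprintf("  assumed airway resistance: %g cmH2O.s/L\n", x$params$rrs))
  med <- median(x$edrs[x$valid], na.rm = TRUE)
  cat(sprintf("  median Edrs over valid samples: %.1f cmH2O/L\n", med))
  invisible(x)
}

#' @export
print.edrs_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  mean inspiratory time: %.2f s", mean(x$ti)))
  if (x$n_dropped > 0L) cat(sprintf("   (%d breaths dropped)", x$n_dropped))
  cat("\n")
  invisible(x)
}

#' Summarise an elastance surface
#'
#' Computes the percentile trajectories, the AUC elastance of each
#' percentile level over the normalised window, the ARDS-like stiffness
#' flag per level, and the 5th-95th percentile band width (median across
#' valid grid points) that quantifies breath-to-breath variability.
#'
#' @param object An [edrs_surface()] or [edrs_fit()].
#' @param levels Percentile levels in percent. Default `c(5, 25, 50, 75, 95)`.
#' @param window AUC window on normalised inspiratory time. Default
#'   `c(0.3, 1)`.
#' @param ... Unused.
#' @return A `summary.edrs_surface` object: list with `percentiles`
#'   (an `edrs_percentiles`), `auc` (named per level, cmH2O.s/L),
#'   `severe` (logical per level), `band_width` (cmH2O/L), `window`,
#'   `patient_id`, `mode`, `n_breaths`.
#' @export
summary.edrs_surface <- function(object, levels = c(5, 25, 50, 75, 95),
                                 window = c(0.3, 1), ...) {
  pct <- percentile_trajectories(object, levels)
  auc <- vapply(seq_along(levels), function(i)
    auc_edrs(pct$traj[i, ], pct$tau, window), numeric(1))
  names(auc) <- paste0("p", levels)
  band <- percentile_trajectories(object, c(5, 95))
  width <- band$traj[2L, ] - band$traj[1L, ]
  structure(list(percentiles = pct, auc = auc,
                 severe = severity_flag(auc),
                 band_width = median(width[band$valid]),
                 window = window, patient_id = object$patient_id,
                 mode = object$mode, n_breaths = pct$n_breaths),
            class = "summary.edrs_surface")
}

#' @export
print.summary.edrs_surface <- function(x, digits = 3, ...) {
  cat(sprintf("Edrs summary - patient %s, mode %s (%d breaths)\n",
              x$patient_id, x$mode, x$n_breaths))
  cat(sprintf("AUC Edrs over normalised inspiration [%.1f, %.1f] (cmH2O.s/L):\n",
              x$window[1L], x$window[2L]))
  tab <- data.frame(percentile = x$percentiles$levels,
                    auc = round(unname(x$auc), digits),
                    ards_like = unname(x$severe))
  print(tab, row.names = FALSE)
  cat(sprintf("5th-95th percentile band width: %.1f cmH2O/L\n", x$band_width))
  invisible(x)
}

#' Extract AUC elastance coefficients
#'
#' The per-patient headline numbers of a fitted surface: AUC of the
#' elastance percentile trajectories over the normalised window, one value
#' per percentile level.
#'
#' @param object An [edrs_surface()] or [edrs_fit()].
#' @param ... Passed to [summary.edrs_surface()] (`levels`, `window`).
#' @return Named numeric vector, cmH2O.s/L.
#' @export
coef.edrs_surface <- function(object, ...) {
  summary(object, ...)$auc
}

#' Effort residuals of a fitted elastance model
#'
#' For each breath, fits the best single constant elastance by least
#' squares (the passive single-compartment model) and returns the pressure
#' residual `paw - peep - rrs*flow - E_const*volume` over the inspiratory
#' window. For a passive breath the residual is flat noise; for an active
#' breath it carries the signature of the (negative) muscular pressure, so
#' it is a crude effort indicator.
#'
#' @param object An [edrs_fit()].
#' @param ... Unused.
#' @return Numeric vector of residual pressures (cmH2O) over all
#'   inspiratory samples, with attribute `breath` giving each sample's
#'   breath index.
#' @export
residuals.edrs_fit <- function(object, ...) {
  rec <- object$record
  rrs <- object$params$rrs
  res <- numeric(0); bid <- integer(0)
  for (b in seq_len(nrow(object$breaths))) {
    br <- object$breaths[b, ]
    win <- br$onset:(br$end_insp - 1L)
    vol <- compute_volume(rec, br)
    pel <- rec$paw[win] - br$peep - rrs * rec$flow[win]
    e_const <- sum(pel * vol) / sum(vol * vol)
    res <- c(res, pel - e_const * vol)
    bid <- c(bid, rep.int(br$index, length(win)))
  }
  attr(res, "breath") <- bid
  res
}

#' Plot an elastance surface
#'
#' `type = "percentiles"` draws the percentile trajectories against
#' normalised inspiratory time; `type = "surface"` draws the
#' breath-by-time elastance map as an image, breaths in acquisition order.
#'
#' @param x An [edrs_surface()] or [edrs_fit()].
#' @param type `"percentiles"` or `"surface"`.
#' @param levels Percentile levels for `type = "percentiles"`.
#' @param ... Passed to the underlying plotting function.
#' @return `x`, invisibly.
#' @export
plot.edrs_surface <- function(x, type = c("percentiles", "surface"),
                              levels = c(5, 25, 50, 75, 95), ...) {
  type <- match.arg(type)
  if (type == "percentiles") {
    pct <- percentile_trajectories(x, levels)
    matplot(pct$tau, t(pct$traj), type = "l", lty = 1,
            col = hcl.colors(length(levels), "Dark 3"),
            xlab = "normalised inspiratory time",
            ylab = expression(E[drs] ~ (cmH[2]*O/L)),
            main = sprintf("%s - %s", x$patient_id, x$mode), ...)
    abline(h = 0, lty = 3)
    legend("bottomright", legend = paste0(levels, "th"), lty = 1,
           col = hcl.colors(length(levels), "Dark 3"), bty = "n")
  } else {
    image(x = x$tau, y = seq_len(nrow(x$edrs)), z = t(x$edrs),
          col = hcl.colors(64, "Viridis"),
          xlab = "normalised inspiratory time", ylab = "breath",
          main = sprintf("%s - %s", x$patient_id, x$mode), ...)
  }
  invisible(x)
}
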