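#' Coupling interval: p52 onset time after stimulation
#'
#' The coupling interval is the lag between canonical pathway activation
#' (stimulus onset, t = 0) and noncanonical p52 formation.  It is measured
#' as the earliest time at which the p52 rise above its pre-stimulus level
#' reaches a fraction \code{theta} of a fixed reference rise, located by
#' linear interpolation between output samples.  The reference
#' \code{p52_ref_rise} is the nominal run's plateau rise (p52 at 600 min
#' minus p52 at 0), frozen across a scan so intervals are comparable between
#' runs.
#'
#' @param traj an \code{nfkb_trajectory} (or list with \code{times_min} and a
#'   p52 column in \code{values}).
#' @param theta threshold fraction in (0, 1); default 0.10.
#' @param p52_ref_rise reference plateau rise, a.u. (> 0).
#' @return Onset time in minutes, or \code{NA_real_} (no-onset sentinel) if
#'   the threshold is never crossed by the end of the trajectory.
#' @seealso \code{\link{p52_plateau_rise}}
#' @export
coupling_interval <- function(traj, theta = 0.10, p52_ref_rise) {
  if (!is.numeric(theta) || theta <= 0 || theta >= 1) {
    stop("theta must lie strictly between 0 and 1")
  }
  if (!is.numeric(p52_ref_rise) || p52_ref_rise <= 0) {
    stop("p52_ref_rise must be > 0")
  }
  times <- traj$times_min
  if (max(times) < 600) {
    warning("trajectory shorter than 600 min; scan intervals may be censored")
  }
  p52 <- traj$values[, "p52"] - traj$values[1, "p52"]
  thr <- theta * p52_ref_rise
  k <- which(p52 >= thr)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1) return(0)
  # linear interpolation between the bracketing samples
  times[k - 1] + (thr - p52[k - 1]) / (p52[k] - p52[k - 1]) *
    (times[k] - times[k - 1])
}

#' Nominal p52 plateau rise
#'
#' Reference rise used by the coupling-interval statistic: p52 at
#' \code{t_ref_min} minus p52 at stimulus onset, from a run at the given
#' (usually nominal) delays.
#'
#' @param params parameter vector.
#' @param t_ref_min reference time, minutes (default 600 = 10 h).
#' @param ... passed to \code{\link{simulate_model}}.
#' @return The rise in a.u., with the trajectory attached as attribute
#'   \code{"trajectory"}.
#' @export
p52_plateau_rise <- function(params, t_ref_min = 600, ...) {
  traj <- simulate_model(params, t_end_min = t_ref_min, ...)
  p52 <- traj$values[, "p52"]
  structure(unname(p52[length(p52)] - p52[1]), trajectory = traj)
}
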