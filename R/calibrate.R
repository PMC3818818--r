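# Deterministic calibration of the reduced model to the study's printed
# timing facts.  The search is a fixed-seed Nelder-Mead refinement in log
# space around a supplied starting point, preceded (optionally) by a coarse
# log-grid sweep of the most timing-critical rates; identical inputs give
# bit-identical output.

.calib_free_default <- c(
  "ikba_deg_by_ikk", "ikba_rela_assoc", "txn_max_ikba", "tln_rate_ikba",
  "deg_ikba", "hill_K_rela", "txn_max_traf1", "txn_max_p100",
  "tln_rate_traf1", "deg_traf1", "traf1_nik_bind", "nik_synth_rate",
  "nik_stable_deg", "tln_rate_p100", "deg_p100", "proc_rate", "proc_K",
  "deg_p52", "deg_mrna", "ikk_act_rate", "ikk_inact_rate")

#' Measure the calibration summary statistics of a parameter set
#'
#' Computes the quantities the calibration targets constrain: the coupling
#' interval at the nominal delays (120, 90), at (0, 0), the TRAF1-axis
#' plateau behaviour at a few probe delays, and the canonical reporter first
#' peak time.
#'
#' @param params parameter vector.
#' @param theta threshold fraction for the interval statistic.
#' @param h_min internal integration step, minutes.
#' @return List with \code{interval_nominal_min}, \code{interval_zero_min},
#'   \code{axis_intervals_min} (named by TRAF1 probe delay, NF-kB2 fixed at
#'   90), \code{reporter_peak_min} and \code{ref_rise}.
#' @export
calibration_summary <- function(params, theta = 0.10, h_min = 0.05) {
  p <- validate_params(params)
  nom <- .simulate_at_delays(p, 120, 90, dt_out_min = 1, h_min = h_min)
  ref <- unname(nom$values[nrow(nom$values), "p52"] - nom$values[1, "p52"])
  iv <- function(t1, t2) {
    coupling_interval(.simulate_at_delays(p, t1, t2, dt_out_min = 1,
                                          h_min = h_min), theta, ref)
  }
  probes <- c(0, 15, 30, 45, 60, 75, 90, 105)
  ax <- vapply(probes, function(t1) iv(t1, 90), numeric(1))
  names(ax) <- probes
  list(interval_nominal_min = iv(120, 90),
       interval_zero_min = iv(0, 0),
       axis_intervals_min = ax,
       reporter_peak_min = nom$times_min[
         which.max(nom$values[, "CanonReporter_mRNA"])],
       ref_rise = ref)
}

.calibration_loss <- function(m) {
  if (any(!is.finite(c(m$interval_nominal_min, m$interval_zero_min))) ||
      any(is.na(m$axis_intervals_min))) {
    return(1e6)
  }
  pl <- m$axis_intervals_min[as.character(c(0, 15, 30, 45, 60, 75, 90))]
  spread <- max(pl) - min(pl)
  brk <- m$axis_intervals_min[["105"]] - m$axis_intervals_min[["90"]]
  ((m$interval_nominal_min - 360) / 15)^2 +
    40 * max(0, m$interval_zero_min - 13)^2 +
    6 * max(0, spread - 5)^2 +
    6 * max(0, 12 - brk)^2 +
    10 * max(0, m$reporter_peak_min - 55)^2 +
    0.5 * max(0, abs(log10(m$ref_rise) - 0.5) - 1.5)^2
}

#' Calibrate the model to the nominal timing targets
#'
#' Deterministic search for a parameter set realizing the study's printed
#' timing facts: coupling interval of 360 min at the nominal delays
#' (120, 90), at most one 15-min grid step at (0, 0), a TRAF1-axis plateau
#' for delays in [0, 90] with the NF-kB2 delay at 90, and a canonical
#' reporter first peak within the first hour.  Starting from \code{start},
#' a fixed-seed Nelder-Mead refinement is run in log-parameter space with
#' seeded perturbation restarts; the procedure is a pure function of its
#' arguments (bit-stable).  The shipped default configuration is the output
#' of this routine.
#'
#' @param start starting parameter vector.
#' @param free names of parameters the search may move.
#' @param maxit Nelder-Mead iteration budget per restart round.
#' @param restarts number of perturbation restarts.
#' @param seed RNG seed for the restart perturbations.
#' @param tol loss value at which the search stops early.
#' @param h_min internal integration step, minutes.
#' @param must_meet_targets when \code{TRUE} (default) the routine fails,
#'   listing the best residuals, if the timing targets are not met within
#'   one grid step; \code{FALSE} returns the best parameter set found,
#'   which is how the shipped configuration was produced.
#' @return Calibrated parameter vector of class \code{nfkb_params}, with the
#'   achieved summary attached as attribute \code{"summary"}.
#' @export
calibrate_nominal <- function(start = default_params(),
                              free = .calib_free_default,
                              maxit = 400, restarts = 2, seed = 1L,
                              tol = 0.5, h_min = 0.05,
                              must_meet_targets = TRUE) {
  p0 <- validate_params(start)
  v0 <- log(unname(p0[free]))
  obj <- function(logv) {
    if (any(abs(logv - v0) > 8)) return(1e6)
    p <- p0
    p[free] <- exp(logv)
    m <- try(calibration_summary(p, h_min = h_min), silent = TRUE)
    if (inherits(m, "try-error")) return(1e6)
    .calibration_loss(m)
  }
  best <- list(v = v0, val = obj(v0))
  v <- v0
  set.seed(seed)
  for (round in seq_len(restarts + 1)) {
    fit <- stats::optim(v, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-9))
    if (fit$value < best$val) best <- list(v = fit$par, val = fit$value)
    if (best$val < tol) break
    v <- best$v + stats::rnorm(length(v0), 0, 0.3)
  }
  out <- p0
  out[free] <- exp(best$v)
  out <- structure(out[.param_order], class = "nfkb_params")
  m <- calibration_summary(out, h_min = h_min)
  if (must_meet_targets &&
      (.calibration_loss(m) >= 1e6 ||
       abs(m$interval_nominal_min - 360) > 15 || m$interval_zero_min > 15)) {
    stop(sprintf(paste0(
      "calibration infeasible from this starting point: ",
      "interval(120,90) = %.1f min (target 360 +/- 15), ",
      "interval(0,0) = %.1f min (target <= 15), reporter peak = %g min"),
      m$interval_nominal_min, m$interval_zero_min, m$reporter_peak_min))
  }
  attr(out, "summary") <- m
  out
}
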