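#' Specification of a translational-delay scan
#'
#' The delay lattice spans 0-10 h in 15-min increments by default, following
#' the study design in which each delay was altered by the addition or
#' subtraction of 15 min around its nominal value.
#'
#' @param grid_min,grid_max,grid_step lattice bounds and step, minutes.
#' @param axes \code{"traf1_only"}, \code{"nfkb2_only"} or \code{"both"}.
#' @param include_nominal_baseline add one nominal-delay baseline run (single
#'   axis scans; default \code{TRUE}).  The baseline also supplies the
#'   scan-wide p52 reference rise.
#' @param fixed_other_delay_min the delay held fixed in single-axis scans;
#'   default: nominal value of the other protein.
#' @return List of class \code{delay_scan_spec}.
#' @export
delay_scan_spec <- function(grid_min = 0, grid_max = 600, grid_step = 15,
                            axes = c("traf1_only", "nfkb2_only", "both"),
                            include_nominal_baseline = TRUE,
                            fixed_other_delay_min = NULL) {
  axes <- match.arg(axes)
  if (grid_step <= 0) stop("grid_step must be > 0")
  if (grid_min > grid_max) stop("grid_min must be <= grid_max")
  if (grid_min < 0 || grid_max > 600) {
    stop("delay grid must lie within the study span [0, 600] minutes")
  }
  if (abs((grid_max - grid_min) / grid_step -
          round((grid_max - grid_min) / grid_step)) > 1e-9) {
    stop("(grid_max - grid_min) must be divisible by grid_step")
  }
  structure(list(grid_min = grid_min, grid_max = grid_max,
                 grid_step = grid_step, axes = axes,
                 include_nominal_baseline = include_nominal_baseline,
                 fixed_other_delay_min = fixed_other_delay_min),
            class = "delay_scan_spec")
}

.scan_grid <- function(spec) seq(spec$grid_min, spec$grid_max, by = spec$grid_step)

.simulate_at_delays <- function(params, tau1, tau2, dt_out_min = 5, h_min = 0.05) {
  p <- params
  p[["tau_traf1_min"]] <- tau1
  p[["tau_nfkb2_min"]] <- tau2
  simulate_model(p, t_end_min = 600, dt_out_min = dt_out_min, h_min = h_min)
}

.new_scan_result <- function(records, n_runs, theta, params) {
  structure(list(records = records, n_runs = n_runs, threshold_theta = theta,
                 params_snapshot = params), class = "nfkb_scan")
}

#' Single-axis translational-delay scan
#'
#' Runs one simulation per lattice value of the chosen delay, holding the
#' other delay fixed, plus one nominal-baseline run when requested (the
#' study's 41 lattice runs + 1 baseline = 42 simulations per protein).  All
#' intervals use the scan-wide p52 reference rise from the baseline run at
#' nominal delays.
#'
#' @param params parameter vector.
#' @param spec a \code{\link{delay_scan_spec}} with axes \code{"traf1_only"}
#'   or \code{"nfkb2_only"}.
#' @param theta threshold fraction for the coupling interval.
#' @param dt_out_min,h_min simulation output grid and internal step, minutes.
#' @return Object of class \code{nfkb_scan}: \code{records} (data frame with
#'   \code{tau_traf1_min}, \code{tau_nfkb2_min},
#'   \code{coupling_interval_min}, NA = no onset), \code{n_runs},
#'   \code{threshold_theta}, \code{params_snapshot}.
#' @export
scan_single_delay <- function(params, spec = delay_scan_spec(), theta = 0.10,
                              dt_out_min = 5, h_min = 0.05) {
  if (!inherits(spec, "delay_scan_spec")) stop("spec must be a delay_scan_spec()")
  if (spec$axes == "both") stop("use scan_combinatorial() for axes = 'both'")
  p <- validate_params(params)
  nom1 <- p[["tau_traf1_min"]]
  nom2 <- p[["tau_nfkb2_min"]]
  other <- spec$fixed_other_delay_min
  if (is.null(other)) other <- if (spec$axes == "traf1_only") nom2 else nom1

  nom_traj <- .simulate_at_delays(p, nom1, nom2, dt_out_min, h_min)
  ref_rise <- unname(nom_traj$values[nrow(nom_traj$values), "p52"] -
                     nom_traj$values[1, "p52"])

  grid <- .scan_grid(spec)
  rows <- lapply(grid, function(tau) {
    tau1 <- if (spec$axes == "traf1_only") tau else other
    tau2 <- if (spec$axes == "traf1_only") other else tau
    traj <- .simulate_at_delays(p, tau1, tau2, dt_out_min, h_min)
    data.frame(tau_traf1_min = tau1, tau_nfkb2_min = tau2,
               coupling_interval_min = coupling_interval(traj, theta, ref_rise))
  })
  n_runs <- length(grid)
  if (spec$include_nominal_baseline) {
    rows <- c(rows, list(data.frame(
      tau_traf1_min = nom1, tau_nfkb2_min = nom2,
      coupling_interval_min = coupling_interval(nom_traj, theta, ref_rise))))
    n_runs <- n_runs + 1
  }
  records <- do.call(rbind, rows)
  records$baseline <- c(rep(FALSE, length(grid)),
                        if (spec$include_nominal_baseline) TRUE)
  .new_scan_result(records, as.integer(n_runs), theta, p)
}

#' Combinatorial two-delay scan
#'
#' One simulation per (TRAF1 delay, NF-kB2 delay) lattice pair: the default
#' 0-600 min lattice in 15-min steps gives the study's 41 x 41 = 1681
#' combinatorial simulations.  Intervals use the nominal-run p52 reference
#' rise, frozen across the scan.
#'
#' @inheritParams scan_single_delay
#' @return Object of class \code{nfkb_scan}; \code{records} holds the
#'   complete Cartesian product.
#' @export
scan_combinatorial <- function(params, spec = delay_scan_spec(axes = "both"),
                               theta = 0.10, dt_out_min = 5, h_min = 0.05) {
  if (!inherits(spec, "delay_scan_spec")) stop("spec must be a delay_scan_spec()")
  if (spec$axes != "both") stop("spec$axes must be 'both'")
  p <- validate_params(params)
  nom_traj <- .simulate_at_delays(p, p[["tau_traf1_min"]], p[["tau_nfkb2_min"]],
                                  dt_out_min, h_min)
  ref_rise <- unname(nom_traj$values[nrow(nom_traj$values), "p52"] -
                     nom_traj$values[1, "p52"])
  grid <- .scan_grid(spec)
  combos <- expand.grid(tau_traf1_min = grid, tau_nfkb2_min = grid,
                        KEEP.OUT.ATTRS = FALSE)
  iv <- vapply(seq_len(nrow(combos)), function(i) {
    traj <- .simulate_at_delays(p, combos$tau_traf1_min[i],
                                combos$tau_nfkb2_min[i], dt_out_min, h_min)
    coupling_interval(traj, theta, ref_rise)
  }, numeric(1))
  combos$coupling_interval_min <- iv
  .new_scan_result(combos, as.integer(nrow(combos)), theta, p)
}

#' @export
print.nfkb_scan <- function(x, ...) {
  iv <- x$records$coupling_interval_min
  cat(sprintf("Delay scan: %d runs, theta = %g; interval range %g-%g min (%d no-onset)\n",
              x$n_runs, x$threshold_theta,
              suppressWarnings(min(iv, na.rm = TRUE)),
              suppressWarnings(max(iv, na.rm = TRUE)), sum(is.na(iv))))
  invisible(x)
}

#' Write scan records as CSV
#'
#' Columns \code{tau_traf1_min,tau_nfkb2_min,coupling_interval_min}; the
#' no-onset sentinel is written as \code{NA}.
#'
#' @param scan an \code{nfkb_scan}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  cols <- c("tau_traf1_min", "tau_nfkb2_min", "coupling_interval_min")
  utils::write.csv(scan$records[, cols], path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Contour-ready dense matrix of a combinatorial scan
#'
#' Rows = TRAF1 delay, columns = NF-kB2 delay.  When \code{path} is given the
#' matrix is also written as a TSV with row/column labels.
#'
#' @param scan an \code{nfkb_scan} from \code{\link{scan_combinatorial}}.
#' @param path optional output TSV path.
#' @return The dense interval matrix, invisibly when written.
#' @export
scan_contour_matrix <- function(scan, path = NULL) {
  r <- scan$records
  t1 <- sort(unique(r$tau_traf1_min))
  t2 <- sort(unique(r$tau_nfkb2_min))
  m <- matrix(NA_real_, length(t1), length(t2), dimnames = list(t1, t2))
  m[cbind(match(r$tau_traf1_min, t1), match(r$tau_nfkb2_min, t2))] <-
    r$coupling_interval_min
  if (!is.null(path)) {
    utils::write.table(data.frame(tau_traf1_min = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    return(invisible(m))
  }
  m
}

#' Largest delay below which the coupling interval has plateaued
#'
#' Given a single-axis scan, returns the largest lattice value \code{tau}
#' such that the interval is constant (within \code{tol_min}) over all
#' lattice delays \code{<= tau}.  Applied to the TRAF1 axis with the NF-kB2
#' delay at its nominal 90 min this identifies the critical threshold below
#' which further reduction of the TRAF1 delay no longer shortens coupling.
#'
#' @param scan an \code{nfkb_scan} from \code{\link{scan_single_delay}}.
#' @param tol_min constancy tolerance, minutes (default 7.5 = half a grid
#'   step, the interpolation tolerance).
#' @return Lattice value in minutes.
#' @export
plateau_threshold <- function(scan, tol_min = 7.5) {
  r <- scan$records[!isTRUE(scan$records$baseline) & !scan$records$baseline, , drop = FALSE]
  axis <- if (length(unique(r$tau_traf1_min)) > 1) "tau_traf1_min" else "tau_nfkb2_min"
  r <- r[order(r[[axis]]), ]
  iv <- r$coupling_interval_min
  if (is.na(iv[1])) stop("no onset at the smallest delay; plateau undefined")
  best <- r[[axis]][1]
  for (k in seq_along(iv)) {
    seg <- iv[1:k]
    if (any(is.na(seg)) || max(seg) - min(seg) > tol_min) break
    best <- r[[axis]][k]
  }
  best
}

#' Classify a delay combination into the study's kinetic regimes
#'
#' Literal implementation of the three-row conceptual decision table for
#' NF-kB2/p100 processing kinetics (rows evaluated in order, first match
#' wins): both delays below nominal is \code{"fast"}; holding one delay at
#' nominal with the other at or below nominal is \code{"nominal"}; the
#' remaining combinations are \code{"delayed"}.
#'
#' @param tau_traf1_min TRAF1 translational delay, minutes (>= 0).
#' @param tau_nfkb2_min NF-kB2 translational delay, minutes (>= 0).
#' @return One of \code{"fast"}, \code{"nominal"}, \code{"delayed"}.
#' @examples
#' classify_regime(60, 60)    # fast
#' classify_regime(120, 90)   # nominal
#' classify_regime(180, 120)  # delayed
#' @export
classify_regime <- function(tau_traf1_min, tau_nfkb2_min) {
  if (tau_traf1_min < 0 || tau_nfkb2_min < 0) stop("delays must be >= 0")
  t1 <- tau_traf1_min
  t2 <- tau_nfkb2_min
  if (t1 < 120 && t2 < 90) return("fast")
  if ((t1 <= 120 && t2 == 90) || (t1 == 120 && t2 <= 90)) return("nominal")
  if ((t1 >= 120 && t2 > 90) || (t1 > 120 && t2 <= 90) ||
      (t1 <= 120 && t2 > 90)) {
    return("delayed")
  }
  stop("unclassifiable delay pair")  # unreachable: rows cover the quadrant
}
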