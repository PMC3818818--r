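#' Precompute noise-free p52 series over the delay lattice
#'
#' Simulates the model once per lattice pair and stores the p52 series; the
#' result is reused by \code{\link{recover_delays}} so that repeated
#' recoveries (e.g. across noise seeds) cost one grid of simulations total.
#'
#' @param params parameter vector (non-delay parameters assumed known).
#' @param grid lattice of candidate delays, minutes.
#' @param dt_out_min output sampling interval, minutes.
#' @param h_min internal integration step, minutes.
#' @return List with \code{grid}, \code{times_min} and \code{p52} (matrix,
#'   one column per (tau1, tau2) pair in row-major \code{expand.grid} order),
#'   plus \code{pairs} (the matching data frame of delay pairs).
#' @export
precompute_p52_grid <- function(params, grid = seq(0, 600, by = 15),
                                dt_out_min = 15, h_min = 0.05) {
  p <- validate_params(params)
  pairs <- expand.grid(tau_traf1_min = grid, tau_nfkb2_min = grid,
                       KEEP.OUT.ATTRS = FALSE)
  p52 <- vapply(seq_len(nrow(pairs)), function(i) {
    traj <- .simulate_at_delays(p, pairs$tau_traf1_min[i],
                                pairs$tau_nfkb2_min[i], dt_out_min, h_min)
    unname(traj$values[, "p52"])
  }, numeric(600 / dt_out_min + 1))
  list(grid = grid, times_min = seq(0, 600, by = dt_out_min), p52 = p52,
       pairs = pairs)
}

#' Recover the two translational delays from an observed p52 series
#'
#' Grid search over the 15-min delay lattice minimizing the sum of squared
#' deviations between the observed p52 series and the model's noise-free
#' series, all non-delay parameters known.  Candidates whose SSE is within
#' \code{sse_tol} of the minimum are treated as ties and resolved to the
#' lexicographically smallest (TRAF1 delay, NF-kB2 delay) pair.
#'
#' @param observed numeric p52 series sampled on \code{times_min}, or a list
#'   with elements \code{times_min} and \code{p52}.
#' @param params parameter vector used to generate the candidates.
#' @param grid candidate delay lattice, minutes.
#' @param precomputed optional output of \code{\link{precompute_p52_grid}}
#'   (must match \code{params} and \code{grid}).
#' @param sse_tol absolute SSE tie tolerance (documented tie-break knob).
#' @param dt_out_min,h_min simulation settings when \code{precomputed} is
#'   absent.
#' @return Named numeric vector \code{c(tau_traf1_min, tau_nfkb2_min)} with
#'   the SSE surface attached as attribute \code{"sse"}.
#' @export
recover_delays <- function(observed, params, grid = seq(0, 600, by = 15),
                           precomputed = NULL, sse_tol = 1e-12,
                           dt_out_min = 15, h_min = 0.05) {
  if (is.list(observed)) {
    times <- observed$times_min
    y <- observed$p52
  } else {
    y <- as.numeric(observed)
    times <- seq(0, by = dt_out_min, length.out = length(y))
  }
  if (max(times) < 600) stop("observed series must cover at least 600 min")
  if (is.null(precomputed)) {
    precomputed <- precompute_p52_grid(params, grid, dt_out_min = dt_out_min,
                                       h_min = h_min)
  }
  if (!isTRUE(all.equal(precomputed$times_min, times))) {
    stop("observed sampling grid does not match the precomputed series")
  }
  sse <- colSums((precomputed$p52 - y)^2)
  best <- min(sse)
  tied <- which(sse <= best + sse_tol)
  pairs <- precomputed$pairs[tied, , drop = FALSE]
  ord <- order(pairs$tau_traf1_min, pairs$tau_nfkb2_min)
  pick <- pairs[ord[1], ]
  structure(c(tau_traf1_min = pick$tau_traf1_min,
              tau_nfkb2_min = pick$tau_nfkb2_min),
            sse = stats::setNames(sse, paste(precomputed$pairs$tau_traf1_min,
                                             precomputed$pairs$tau_nfkb2_min,
                                             sep = "/")))
}
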