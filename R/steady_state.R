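#' Pre-stimulus steady state of the model
#'
#' With no stimulus the IKK activation term vanishes, so active IKK and free
#' nuclear RelA relax to zero and RelA is fully sequestered by IkBa.  The
#' remaining fixed point then follows in closed form down the cascade, except
#' for the TRAF1/NIK pair (coupled through second-order complex formation)
#' and p100 (second-order processing), each solved by safeguarded
#' root-finding on one scalar equation.  The returned state is the constant
#' history used for all lagged reads at t < 0.
#'
#' @param params parameter vector (see \code{\link{model_params}}).
#' @param tol residual tolerance on time derivatives, a.u./min.
#' @return Named numeric state vector (14 species).
#' @export
steady_state <- function(params, tol = 1e-8) {
  p <- validate_params(params)
  y <- stats::setNames(numeric(length(.species_names)), .species_names)

  Mb <- p[["basal_txn"]] / p[["deg_mrna"]]
  y["IkBa_mRNA"] <- y["CanonReporter_mRNA"] <- y["TRAF1_mRNA"] <- y["p100_mRNA"] <- Mb
  y["IkBa_protein"] <- p[["tln_rate_ikba"]] * Mb / p[["deg_ikba"]]
  y["RelA_IkBa_complex"] <- p[["rela_total"]]
  y["RelA_nuclear"] <- 0

  # TRAF1/NIK pair: translation inflow balances decay plus complex formation,
  # with NIK at its own balance given TRAF1.
  influx <- p[["tln_rate_traf1"]] * Mb
  nik_at <- function(T) {
    p[["nik_synth_rate"]] / (p[["nik_fast_deg"]] + p[["traf1_nik_bind"]] * T)
  }
  fT <- function(T) {
    influx - p[["deg_traf1"]] * T - p[["traf1_nik_bind"]] * T * nik_at(T)
  }
  Tmax <- influx / max(p[["deg_traf1"]], 1e-12) + influx / max(p[["nik_fast_deg"]], 1e-12) + 1
  T <- if (influx == 0) 0 else stats::uniroot(fT, c(0, Tmax), tol = 1e-15)$root
  N <- nik_at(T)
  capture <- p[["traf1_nik_bind"]] * T * N
  C <- capture / p[["nik_stable_deg"]]
  y["TRAF1_protein"] <- T
  y["NIK_free"] <- N
  y["TRAF1_NIK_complex"] <- C

  # p100: translation inflow balances cooperative processing plus decay.
  pin <- p[["tln_rate_p100"]] * Mb
  proc_flux <- function(P) {
    p[["proc_rate"]] * C * P^2 / (p[["proc_K"]] + P)
  }
  fP <- function(P) pin - proc_flux(P) - p[["deg_p100"]] * P
  P <- if (pin == 0) 0 else {
    stats::uniroot(fP, c(0, pin / p[["deg_p100"]] + 1), tol = 1e-15)$root
  }
  y["p100_protein"] <- P
  y["p52"] <- proc_flux(P) / p[["deg_p52"]]

  Hp <- .hill(y[["p52"]], p[["hill_K_p52"]], p[["hill_h"]])
  y["TNIP1_mRNA"] <- (p[["basal_txn"]] + p[["txn_max_tnip1"]] * Hp) / p[["deg_mrna"]]

  res <- model_derivatives(y, p, stimulus = stimulus_program("none"), t = 0)
  if (max(abs(res)) >= tol) {
    worst <- which.max(abs(res))
    stop(sprintf(
      "steady state did not converge: residual d(%s)/dt = %.3e a.u./min",
      .species_names[worst], res[worst]))
  }
  y
}

.hill <- function(x, K, h) {
  if (x <= 0) return(0)
  1 / (1 + (K / x)^h)
}

#' Right-hand side of the reduced model (no delayed reads)
#'
#' Evaluates the 14 rate equations with the lagged mRNA reads replaced by
#' supplied values (defaults: the current values, i.e. the zero-delay
#' limit).  Exposed for steady-state residual checks and for the delay-free
#' cross-checks in the test-suite.
#'
#' @param y named state vector.
#' @param params parameter vector.
#' @param stimulus a \code{\link{stimulus_program}}.
#' @param t time, min.
#' @param traf1_mrna_lag,p100_mrna_lag values of the delayed mRNA reads.
#' @return Numeric vector of time derivatives, a.u./min.
#' @export
model_derivatives <- function(y, params, stimulus = stimulus_program("tnf_step"),
                              t = 0, traf1_mrna_lag = y[["TRAF1_mRNA"]],
                              p100_mrna_lag = y[["p100_mRNA"]]) {
  p <- params
  stim <- if (stimulus$kind == "tnf_step" && t >= stimulus$onset_min) {
    stimulus$amplitude
  } else 0
  Hr <- .hill(y[["RelA_nuclear"]], p[["hill_K_rela"]], p[["hill_h"]])
  Hp <- .hill(y[["p52"]], p[["hill_K_p52"]], p[["hill_h"]])
  assoc <- p[["ikba_rela_assoc"]] * y[["IkBa_protein"]] * y[["RelA_nuclear"]]
  release <- p[["ikba_deg_by_ikk"]] * y[["IKK_active"]] * y[["RelA_IkBa_complex"]]
  capture <- p[["traf1_nik_bind"]] * y[["TRAF1_protein"]] * y[["NIK_free"]]
  proc <- p[["proc_rate"]] * y[["TRAF1_NIK_complex"]] *
    y[["p100_protein"]]^2 / (p[["proc_K"]] + y[["p100_protein"]])

  c(IKK_active = p[["ikk_act_rate"]] * stim * (1 - y[["IKK_active"]]) -
      p[["ikk_inact_rate"]] * y[["IKK_active"]],
    IkBa_mRNA = p[["basal_txn"]] + p[["txn_max_ikba"]] * Hr -
      p[["deg_mrna"]] * y[["IkBa_mRNA"]],
    IkBa_protein = p[["tln_rate_ikba"]] * y[["IkBa_mRNA"]] - assoc -
      p[["deg_ikba"]] * y[["IkBa_protein"]],
    RelA_IkBa_complex = assoc - release,
    RelA_nuclear = release - assoc,
    CanonReporter_mRNA = p[["basal_txn"]] + p[["txn_max_canon_reporter"]] * Hr -
      p[["deg_mrna"]] * y[["CanonReporter_mRNA"]],
    TRAF1_mRNA = p[["basal_txn"]] + p[["txn_max_traf1"]] * Hr -
      p[["deg_mrna"]] * y[["TRAF1_mRNA"]],
    TRAF1_protein = p[["tln_rate_traf1"]] * traf1_mrna_lag -
      p[["deg_traf1"]] * y[["TRAF1_protein"]] - capture,
    NIK_free = p[["nik_synth_rate"]] - p[["nik_fast_deg"]] * y[["NIK_free"]] - capture,
    TRAF1_NIK_complex = capture - p[["nik_stable_deg"]] * y[["TRAF1_NIK_complex"]],
    p100_mRNA = p[["basal_txn"]] + p[["txn_max_p100"]] * Hr -
      p[["deg_mrna"]] * y[["p100_mRNA"]],
    p100_protein = p[["tln_rate_p100"]] * p100_mrna_lag - proc -
      p[["deg_p100"]] * y[["p100_protein"]],
    p52 = proc - p[["deg_p52"]] * y[["p52"]],
    TNIP1_mRNA = p[["basal_txn"]] + p[["txn_max_tnip1"]] * Hp -
      p[["deg_mrna"]] * y[["TNIP1_mRNA"]])
}
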