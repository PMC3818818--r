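# Independent oracles used across the suite.

# First-order (explicit Euler) fixed-step integrator for the delayed model,
# written directly from the rate equations with a ring-buffer history for
# the two lagged mRNA reads.  Deliberately independent of the package's
# RK4 integrator in src/.
# Richardson extrapolation of two Euler passes: cancels the oracle's own
# first-order truncation error while remaining independent of the package's
# RK4 integrator.
euler_oracle_extrapolated <- function(params, t_end_min, dt_out_min, h = 0.01) {
  e1 <- euler_dde_oracle(params, t_end_min, dt_out_min, h = h)
  e2 <- euler_dde_oracle(params, t_end_min, dt_out_min, h = h / 2)
  2 * e2 - e1
}

euler_dde_oracle <- function(params, t_end_min, dt_out_min, h = 0.01,
                             amplitude = 1, onset = 0) {
  p <- as.list(params)
  y0 <- steady_state(params)
  n_steps <- round(t_end_min / h)
  sub <- round(dt_out_min / h)
  lag1 <- round(p$tau_traf1_min / h)
  lag2 <- round(p$tau_nfkb2_min / h)
  buflen <- max(lag1, lag2, 1) + 1
  ring_t <- rep(y0[["TRAF1_mRNA"]], buflen)   # ring buffers of past mRNA
  ring_p <- rep(y0[["p100_mRNA"]], buflen)
  y <- y0
  hillf <- function(x, K, hh) if (x <= 0) 0 else 1 / (1 + (K / x)^hh)
  out <- matrix(NA_real_, n_steps / sub + 1, length(y0),
                dimnames = list(NULL, names(y0)))
  out[1, ] <- y
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * h
    pos <- (i - 1) %% buflen + 1
    m1 <- if (lag1 == 0) y[["TRAF1_mRNA"]] else {
      ring_t[(i - 1 - lag1) %% buflen + 1]
    }
    m2 <- if (lag2 == 0) y[["p100_mRNA"]] else {
      ring_p[(i - 1 - lag2) %% buflen + 1]
    }
    stim <- if (t >= onset) amplitude else 0
    Hr <- hillf(y[["RelA_nuclear"]], p$hill_K_rela, p$hill_h)
    Hp <- hillf(y[["p52"]], p$hill_K_p52, p$hill_h)
    assoc <- p$ikba_rela_assoc * y[["IkBa_protein"]] * y[["RelA_nuclear"]]
    release <- p$ikba_deg_by_ikk * y[["IKK_active"]] * y[["RelA_IkBa_complex"]]
    capture <- p$traf1_nik_bind * y[["TRAF1_protein"]] * y[["NIK_free"]]
    proc <- p$proc_rate * y[["TRAF1_NIK_complex"]] *
      y[["p100_protein"]]^2 / (p$proc_K + y[["p100_protein"]])
    dy <- c(
      p$ikk_act_rate * stim * (1 - y[["IKK_active"]]) -
        p$ikk_inact_rate * y[["IKK_active"]],
      p$basal_txn + p$txn_max_ikba * Hr - p$deg_mrna * y[["IkBa_mRNA"]],
      p$tln_rate_ikba * y[["IkBa_mRNA"]] - assoc - p$deg_ikba * y[["IkBa_protein"]],
      assoc - release,
      release - assoc,
      p$basal_txn + p$txn_max_canon_reporter * Hr - p$deg_mrna * y[["CanonReporter_mRNA"]],
      p$basal_txn + p$txn_max_traf1 * Hr - p$deg_mrna * y[["TRAF1_mRNA"]],
      p$tln_rate_traf1 * m1 - p$deg_traf1 * y[["TRAF1_protein"]] - capture,
      p$nik_synth_rate - p$nik_fast_deg * y[["NIK_free"]] - capture,
      capture - p$nik_stable_deg * y[["TRAF1_NIK_complex"]],
      p$basal_txn + p$txn_max_p100 * Hr - p$deg_mrna * y[["p100_mRNA"]],
      p$tln_rate_p100 * m2 - proc - p$deg_p100 * y[["p100_protein"]],
      proc - p$deg_p52 * y[["p52"]],
      p$basal_txn + p$txn_max_tnip1 * Hp - p$deg_mrna * y[["TNIP1_mRNA"]])
    y <- pmax(y + h * dy, 0)
    # store the state reached at step i (time i*h) for future lagged reads
    ring_t[i %% buflen + 1] <- y[["TRAF1_mRNA"]]
    ring_p[i %% buflen + 1] <- y[["p100_mRNA"]]
    if (i %% sub == 0) out[i / sub + 1, ] <- y
  }
  out
}

# Delay-free right-hand side for deSolve::ode (zero-delay cross-check).
delay_free_rhs <- function(t, y, parms) {
  names(y) <- model_species()
  list(unname(model_derivatives(y, parms$p, stimulus = parms$stim, t = t)))
}

# Shared expensive fixtures (computed once per test run).
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

get_nominal_traj <- function() fixture("nominal_traj", {
  simulate_model(default_params(), t_end_min = 600, dt_out_min = 1)
})

get_ref_rise <- function() {
  traj <- get_nominal_traj()
  unname(traj$values[nrow(traj$values), "p52"] - traj$values[1, "p52"])
}

get_traf1_scan <- function() fixture("traf1_scan", {
  scan_single_delay(default_params(), delay_scan_spec(axes = "traf1_only"))
})

get_nfkb2_scan <- function() fixture("nfkb2_scan", {
  scan_single_delay(default_params(), delay_scan_spec(axes = "nfkb2_only"))
})

get_grid_scan <- function() fixture("grid_scan", {
  scan_combinatorial(default_params(), delay_scan_spec(axes = "both"))
})
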