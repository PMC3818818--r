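test_that("parameter validation rejects invalid sets", {
  expect_error(model_params(deg_mrna = -0.1), "negative")
  expect_error(model_params(hill_h = 0.5), "hill_h")
  expect_error(model_params(tau_traf1_min = 700), "\\[0, 600\\]")
  expect_error(model_params(nonsense = 1), "unknown parameter")
})

test_that("parameter files round-trip exactly", {
  p <- default_params()
  tmp <- tempfile(fileext = ".conf")
  write_params(p, tmp)
  p2 <- read_params(tmp)
  expect_identical(unclass(p2), unclass(p)[names(p2)])
})

test_that("pre-stimulus steady state has vanishing derivatives", {
  p <- default_params()
  ss <- steady_state(p)
  res <- model_derivatives(ss, p, stimulus = stimulus_program("none"))
  expect_lt(max(abs(res)), 1e-8)
  expect_true(all(ss >= 0))
  expect_equal(unname(ss[["RelA_IkBa_complex"]] + ss[["RelA_nuclear"]]),
               unname(p[["rela_total"]]))
})

test_that("zero basal transcription and zero synthesis give the empty fixed point", {
  p <- model_params(basal_txn = 0, nik_synth_rate = 0)
  ss <- steady_state(p)
  inducible <- setdiff(model_species(), "RelA_IkBa_complex")
  expect_true(all(ss[inducible] == 0))
  expect_equal(unname(ss[["RelA_IkBa_complex"]]), unname(p[["rela_total"]]))
})

test_that("the steady state is invariant under 600 min of unstimulated integration", {
  p <- default_params()
  ss <- steady_state(p)
  traj <- simulate_model(p, stimulus_program("none"), t_end_min = 600,
                         dt_out_min = 100)
  final <- traj$values[nrow(traj$values), ]
  scale <- abs(ss) + 1e-12
  expect_lt(max(abs(final - ss) / scale), 1e-6)
})

test_that("RelA is conserved along the stimulated trajectory", {
  traj <- get_nominal_traj()
  total <- traj$values[, "RelA_IkBa_complex"] + traj$values[, "RelA_nuclear"]
  expect_lt(max(abs(total - traj$params[["rela_total"]])) /
              traj$params[["rela_total"]], 1e-6)
})

test_that("trajectory values are finite, nonnegative, and history is constant", {
  traj <- get_nominal_traj()
  expect_true(all(is.finite(traj$values)))
  expect_true(all(traj$values >= 0))
  expect_identical(history_value(traj, "p52", -5),
                   history_value(traj, "p52", -500))
  expect_error(history_value(traj, "p52", 10), "t < 0")
})

test_that("nuclear RelA responds monotonically to stimulus amplitude", {
  p <- default_params()
  hi <- simulate_model(p, stimulus_program("tnf_step", amplitude = 1),
                       t_end_min = 300, dt_out_min = 5)
  lo <- simulate_model(p, stimulus_program("tnf_step", amplitude = 0),
                       t_end_min = 300, dt_out_min = 5)
  expect_true(all(hi$values[, "RelA_nuclear"] >= lo$values[, "RelA_nuclear"] - 1e-12))
})

test_that("IkBa feedback yields a canonical reporter peak within the first hour", {
  traj <- get_nominal_traj()
  reporter <- species_course(traj, "CanonReporter_mRNA")
  expect_lt(traj$times_min[which.max(reporter)], 60)
})

test_that("with zero delays the model matches a delay-free ODE solver", {
  skip_if_not_installed("deSolve")
  p <- model_params(tau_traf1_min = 0, tau_nfkb2_min = 0)
  traj <- simulate_model(p, t_end_min = 300, dt_out_min = 5)
  sol <- deSolve::ode(y = steady_state(p), times = seq(0, 300, 5),
                      func = delay_free_rhs,
                      parms = list(p = p, stim = stimulus_program("tnf_step")),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  ref <- sol[, model_species()]
  scale <- apply(abs(ref), 2, max)
  scale[scale == 0] <- 1
  expect_lt(max(t(abs(traj$values - ref)) / scale), 1e-4)
})

test_that("RK4 integrator agrees with the first-order Euler oracle across delays", {
  p <- default_params()
  sweeps <- list(c(120, 90), c(0, 0), c(240, 30))
  for (d in sweeps) {
    q <- model_params(tau_traf1_min = d[1], tau_nfkb2_min = d[2], base = p)
    traj <- simulate_model(q, t_end_min = 240, dt_out_min = 10)
    orc <- euler_oracle_extrapolated(q, t_end_min = 240, dt_out_min = 10)
    scale <- apply(abs(orc), 2, max)
    scale[scale == 0] <- 1
    expect_lt(max(t(abs(traj$values - orc)) / scale), 1e-3,
              label = sprintf("oracle agreement at delays (%g, %g)", d[1], d[2]))
  }
})

test_that("halving the integration step leaves reported values unchanged", {
  p <- default_params()
  a <- simulate_model(p, t_end_min = 600, dt_out_min = 10, h_min = 0.1)
  b <- simulate_model(p, t_end_min = 600, dt_out_min = 10, h_min = 0.05)
  scale <- apply(abs(a$values), 2, max)
  scale[scale == 0] <- 1
  expect_lt(max(t(abs(a$values - b$values)) / scale), 1e-4)
})

test_that("trajectory TSV writer and reader round-trip", {
  traj <- simulate_model(default_params(), t_end_min = 50, dt_out_min = 10)
  tmp <- tempfile(fileext = ".tsv")
  write_trajectory(traj, tmp)
  back <- read_trajectory(tmp)
  expect_equal(back$times_min, traj$times_min)
  expect_equal(back$values, traj$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})
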