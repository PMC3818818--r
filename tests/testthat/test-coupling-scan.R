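test_that("coupling interval rejects bad thresholds and flat trajectories", {
  flat <- list(times_min = seq(0, 600, 10),
               values = matrix(1, 61, 1, dimnames = list(NULL, "p52")))
  expect_error(coupling_interval(flat, theta = 0, p52_ref_rise = 1), "theta")
  expect_error(coupling_interval(flat, theta = 1.2, p52_ref_rise = 1), "theta")
  expect_error(coupling_interval(flat, p52_ref_rise = 0), "ref_rise")
  expect_identical(coupling_interval(flat, 0.10, p52_ref_rise = 5), NA_real_)
})

test_that("linear p52 ramps cross at the exact analytic time", {
  # p52(t) = p0 + c t crosses theta * ref at T = theta * ref / c exactly
  times <- seq(0, 600, 25)
  c_rate <- 0.013
  traj <- list(times_min = times,
               values = matrix(2 + c_rate * times, ncol = 1,
                               dimnames = list(NULL, "p52")))
  for (theta in c(0.05, 0.10, 0.37)) {
    ref <- 4.2
    expect_equal(coupling_interval(traj, theta, ref), theta * ref / c_rate,
                 tolerance = 1e-12)
  }
})

test_that("short trajectories raise a censoring warning in scan context", {
  times <- seq(0, 300, 10)
  traj <- list(times_min = times,
               values = matrix(times, ncol = 1, dimnames = list(NULL, "p52")))
  expect_warning(coupling_interval(traj, 0.1, 1), "shorter than 600")
})

test_that("single-axis scans execute 41 lattice runs plus one baseline", {
  scan <- get_traf1_scan()
  expect_identical(scan$n_runs, 42L)
  expect_identical(nrow(scan$records), 42L)
  lattice <- scan$records[!scan$records$baseline, ]
  expect_identical(sort(lattice$tau_traf1_min), seq(0, 600, 15))
  expect_true(all(lattice$tau_nfkb2_min == 90))
})

test_that("degenerate single-point grid reproduces the nominal interval", {
  spec <- delay_scan_spec(grid_min = 120, grid_max = 120,
                          include_nominal_baseline = FALSE)
  scan <- scan_single_delay(default_params(), spec)
  expect_identical(scan$n_runs, 1L)
  nominal <- coupling_interval(get_nominal_traj(), 0.10, get_ref_rise())
  expect_equal(scan$records$coupling_interval_min[1], nominal, tolerance = 0.05)
})

test_that("scan grids outside the study span are rejected", {
  expect_error(delay_scan_spec(grid_max = 900), "\\[0, 600\\]")
  expect_error(delay_scan_spec(grid_step = 0), "grid_step")
  expect_error(delay_scan_spec(grid_min = 0, grid_max = 100, grid_step = 15),
               "divisible")
})

test_that("the combinatorial scan covers the full Cartesian lattice exactly once", {
  scan <- get_grid_scan()
  expect_identical(scan$n_runs, 1681L)
  key <- paste(scan$records$tau_traf1_min, scan$records$tau_nfkb2_min)
  expect_identical(anyDuplicated(key), 0L)
  expect_identical(length(key), 41L * 41L)
})

test_that("coupling interval decreases down the TRAF1 axis and plateaus by 90 min", {
  scan <- get_traf1_scan()
  lattice <- scan$records[!scan$records$baseline, ]
  lattice <- lattice[order(lattice$tau_traf1_min), ]
  iv <- lattice$coupling_interval_min
  tau <- lattice$tau_traf1_min
  # plateau on [0, 90]
  expect_lt(max(iv[tau <= 90]) - min(iv[tau <= 90]), 7.5)
  expect_equal(plateau_threshold(scan), 90)
  # monotone non-decreasing in tau (no-onset treated as +Inf), 7.5-min slack
  ivm <- ifelse(is.na(iv), Inf, iv)
  d <- diff(ivm)
  expect_true(all(is.nan(d) | d >= -7.5))
})

test_that("an NF-kB2-axis plateau exists with the TRAF1 delay at nominal", {
  scan <- get_nfkb2_scan()
  lattice <- scan$records[!scan$records$baseline, ]
  lattice <- lattice[order(lattice$tau_nfkb2_min), ]
  iv <- lattice$coupling_interval_min[lattice$tau_nfkb2_min <= 45]
  expect_lt(max(iv) - min(iv), 7.5)
})

test_that("fast-regime lattice points never exceed the nominal interval", {
  scan <- get_grid_scan()
  r <- scan$records
  nominal <- r$coupling_interval_min[r$tau_traf1_min == 120 &
                                     r$tau_nfkb2_min == 90]
  fast <- r[r$tau_traf1_min < 120 & r$tau_nfkb2_min < 90, ]
  expect_true(all(is.na(fast$coupling_interval_min) == FALSE))
  expect_true(all(fast$coupling_interval_min <= nominal + 7.5))
})

test_that("regime classification matches the literal three-row decision table", {
  expect_identical(classify_regime(60, 60), "fast")
  expect_identical(classify_regime(120, 90), "nominal")
  expect_identical(classify_regime(180, 120), "delayed")
  expect_error(classify_regime(-1, 0), ">= 0")
  # exhaustive lattice sweep against an independent statement of the rows
  oracle <- function(t1, t2) {
    if (t1 < 120 && t2 < 90) "fast"
    else if ((t1 <= 120 && t2 == 90) || (t1 == 120 && t2 <= 90)) "nominal"
    else "delayed"
  }
  lattice <- expand.grid(t1 = seq(0, 600, 15), t2 = seq(0, 600, 15))
  got <- mapply(classify_regime, lattice$t1, lattice$t2)
  want <- mapply(oracle, lattice$t1, lattice$t2)
  expect_identical(got, want)
})

test_that("scan CSV and contour exports round-trip with NA sentinels", {
  scan <- get_traf1_scan()
  tmp <- tempfile(fileext = ".csv")
  write_scan_csv(scan, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(back$coupling_interval_min, scan$records$coupling_interval_min)
  grid <- get_grid_scan()
  tmp2 <- tempfile(fileext = ".tsv")
  m <- scan_contour_matrix(grid, tmp2)
  expect_identical(dim(m), c(41L, 41L))
  expect_identical(sum(is.na(m)), sum(is.na(grid$records$coupling_interval_min)))
})
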