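test_that("the adaptive schedule hits every pulse edge and stays economical", {
  ctl <- solver_controls()
  s3 <- sequence_pulse_train(3)
  ts <- schedule_time_steps(s3, ctl)
  h <- diff(ts)
  expect_true(all(h >= ctl$dtMin - 1e-15))
  expect_true(all(h <= ctl$dtMax + 1e-15))
  edges <- pulse_edges(s3)
  expect_true(all(vapply(edges, function(e) any(abs(ts - e) < 1e-12), TRUE)))
  expect_lte(length(ts) - 1, 500)
  # constant-step counterfactual over the same 7.001 s train
  expect_equal(constant_step_count(s3, 2e-6), 3500500)
  # window longer than the pulse: every step at dtMin
  short <- pulse_train(500, 8e-6, 1000, pulseCount = 1)
  ts2 <- schedule_time_steps(short, ctl)
  expect_true(all(abs(diff(ts2) - ctl$dtMin) < 1e-15))
  expect_error(pulse_train(500, 1.1e-3, 1000, 8), "overlap")
})

test_that("a field-independent conductivity converges in one Newton iteration", {
  pf <- fix("frozen")
  m <- fix("box_small")
  st <- tissue_state(nrow(m$tets), pf)
  sol <- solve_potential(m, st, 500, 2e-6, solver_controls(params = pf), pf)
  expect_identical(sol$newtonIterations, 1L)
  # uniform field U / d across the plate gap
  expect_equal(unique(round(sol$Emag)), 50000)
  # doubling the voltage doubles the current exactly (linearity)
  sol2 <- solve_potential(m, st, 1000, 2e-6, solver_controls(params = pf), pf)
  expect_equal(electrode_current(sol2, m), 2 * electrode_current(sol, m),
               tolerance = 1e-12)
})

test_that("FEM current matches the plate oracle under refinement", {
  p <- fix("params")
  tr <- one_pulse()
  oracle <- plate_oracle(tr, gap = 0.01, area = 1e-4, p)
  for (mesh in list(fix("box_small"), fix("box_mid"))) {
    sim <- run_simulation(mesh, tr, p)
    i <- which(sim$times > 4e-6 & sim$times <= 98e-6)
    expect_lt(max(abs(sim$current[i] - oracle$current[i]) /
                    abs(oracle$current[i])), 0.01)
  }
  # oracle closed forms: virgin sigma at the start of the plateau and
  # saturated-poration current with the damage terms off
  pf <- fix("frozen")
  oracleF <- plate_oracle(tr, gap = 0.01, area = 1e-4, pf)
  expect_equal(oracleF$current[2], 0.065 * 5e4 * 1e-4, tolerance = 1e-9)
  pd <- p; pd$Apg <- 0; pd$AT <- 0
  oracleD <- plate_oracle(tr, gap = 0.01, area = 1e-4, pd)
  expect_equal(oracleD$current[10], 0.1483 * 5e4 * 1e-4, tolerance = 1e-6)
})

test_that("newton iteration counts stay low on the two-needle geometry", {
  p <- fix("params")
  m <- fix("needle")
  res <- run_simulation(m, one_pulse(), p)
  expect_lte(stats::median(res$iterations[-1]), 4)
  expect_true(all(res$iterations[-1] <= 25))
  # residual histories decrease monotonically over accepted iterations
  st <- tissue_state(nrow(m$tets), p)
  sol <- solve_potential(m, st, 500, 2e-6, solver_controls(params = p), p)
  expect_true(all(diff(sol$residuals) < 0))
})

test_that("electrode currents balance and agree between estimators", {
  p <- fix("params")
  m <- fix("needle")
  res <- run_simulation(m, one_pulse(), p, until = 20e-6)
  # discrete conservation via Dirichlet reactions at the final step
  st <- tissue_state(nrow(m$tets), p)
  sol <- NULL
  times <- schedule_time_steps(one_pulse(), solver_controls(params = p),
                               until = 20e-6)
  u <- NULL
  for (k in 2:length(times)) {
    sol <- solve_potential(m, st, pulse_voltage(one_pulse(), times[k]),
                           times[k] - times[k - 1],
                           solver_controls(params = p), p, uInit = u)
    st <- sol$state; u <- sol$u
    iA <- electrode_current(sol, m, "ELECTRODE_A", method = "reaction")
    iB <- electrode_current(sol, m, "ELECTRODE_B", method = "reaction")
    expect_lt(abs(iA + iB) / max(abs(iA), 1e-12), 0.005)
  }
  # the magnitude sum bounds and closely matches |signed flux| at plateau
  iMag <- electrode_current(sol, m, "ELECTRODE_A", method = "magnitude")
  iSgn <- electrode_current(sol, m, "ELECTRODE_A", method = "signed")
  expect_gte(iMag, abs(iSgn) - 1e-12)
  expect_lt(abs(iMag - abs(iSgn)) / iMag, 0.005)
})

test_that("a zero drive produces zero current and a virgin state", {
  p <- fix("params")
  m <- fix("box_small")
  silent <- pulse_train(0, 100e-6, 4762, pulseCount = 1)
  res <- run_simulation(m, silent, p)
  expect_true(all(res$current == 0))
  expect_true(all(res$state$p == 0))
  expect_equal(unique(res$state$sigma), p$sigma0)
})

test_that("pulses become repetitive once relaxation separates them", {
  # 500 V, 100 us pulses at 1 Hz: the rest between pulses is much longer
  # than the poration relaxation time, so successive pulses coincide
  p <- fix("params")
  m <- fix("box_small")
  tr <- pulse_train(500, 100e-6, 1, pulseCount = 3)
  res <- run_simulation(m, tr, p)
  period <- 1
  probe <- c(10e-6, 50e-6, 98e-6)
  for (off in probe) {
    i2 <- res$current[which.min(abs(res$times - (period + off)))]
    i3 <- res$current[which.min(abs(res$times - (2 * period + off)))]
    expect_lt(abs(i3 - i2) / abs(i2), 0.01)
  }
})

test_that("solver failure modes carry diagnostics", {
  p <- fix("params")
  m <- fix("box_small")
  st <- tissue_state(nrow(m$tets), p)
  ctl <- solver_controls(params = p, newtonMaxIter = 0)
  err <- tryCatch(solve_potential(m, st, 500, 2e-6, ctl, p),
                  error = function(e) e)
  expect_match(conditionMessage(err), "did not converge")
  expect_true(length(err$residuals) >= 1)
  # a mesh without electrode tags is singular
  m2 <- m
  m2$triTag <- rep("OUTER", length(m$triTag))
  expect_error(solve_potential(m2, st, 500, 2e-6,
                               solver_controls(params = p), p),
               "singular")
})

test_that("simulation results export to CSV with a monotone time column", {
  p <- fix("params")
  res <- run_simulation(fix("box_small"), one_pulse(), p)
  f <- withr::local_tempfile(fileext = ".csv")
  write_simulation_csv(res, f)
  df <- read.csv(f)
  expect_true(all(diff(df$time) > 0))
  expect_named(df, c("time", "applied_voltage", "current",
                     "newton_iterations"))
})
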