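test_that("target poration ramps linearly between the field limits", {
  p <- fix("params")
  expect_equal(target_poration(0, p), 0)
  expect_equal(target_poration(20000, p), 0)
  expect_equal(target_poration(30000, p), 0.5)
  expect_equal(target_poration(40000, p), 1)
  expect_equal(target_poration(1e6, p), 1)
  # vectorised, non-decreasing, continuous across the clamps
  E <- seq(0, 6e4, by = 250)
  v <- target_poration(E, p)
  expect_true(all(diff(v) >= 0))
  expect_lt(max(abs(diff(v))), 2 * 250 / (p$Emax - p$Emin))
  expect_error(target_poration(-1, p), "non-negative")
})

test_that("poration rises instantly and relaxes exponentially", {
  p <- fix("params")
  expect_equal(update_poration(0, 0, 1e-3, p), 0)              # fixed point
  expect_equal(update_poration(1, 0, 100e-6, p), exp(-1),      # one tau
               tolerance = 1e-12)
  expect_equal(update_poration(0.2, 50000, 1e-6, p), 1)        # fast rise
  expect_error(update_poration(1.2, 0, 1e-6, p), "\\[0, 1\\]")
  expect_error(update_poration(0.5, 0, 0, p), "positive")
})

test_that("poration stays in [0,1] under arbitrary update sequences", {
  p <- fix("params")
  set.seed(42)
  for (rep in 1:20) {
    pv <- runif(1)
    for (k in 1:50) {
      pv <- update_poration(pv, runif(1, 0, 1e5), 10^runif(1, -7, -2), p)
      expect_true(pv >= 0 && pv <= 1)
    }
  }
})

test_that("damage indicators grow with the field and decay between pulses", {
  p <- fix("params")
  expect_equal(update_damage(3, 0, 1e-4, TRUE, p$alphaP, p$tauRelax), 3)
  expect_equal(update_damage(0, 50000, 100e-6, TRUE, p$alphaP, p$tauRelax),
               0.0075)
  expect_equal(update_damage(2, 0, 5e-4, FALSE, p$alphaP, 5e-4), 2 * exp(-1))
  # strictly decreasing off-pulse when positive; linear growth on-pulse
  expect_lt(update_damage(1, 1e5, 1e-6, FALSE, p$alphaP, p$tauRelax), 1)
  expect_equal(update_damage(1, 2e4, 2e-6, TRUE, p$alphaP, p$tauRelax) - 1,
               2 * (update_damage(1, 1e4, 2e-6, TRUE, p$alphaP, p$tauRelax) - 1))
  expect_error(update_damage(-0.1, 0, 1e-6, TRUE, p$alphaP, p$tauRelax),
               "non-negative")
})

test_that("conductivity has the virgin, porated and saturated values", {
  p <- fix("params")
  expect_equal(conductivity(0, 0, 0, p), 0.065)
  expect_equal(conductivity(1, 0, 0, p), 0.1483)
  expect_equal(conductivity(1, 1e9, 1e9, p), 0.1483 * 1.35 * 1.125,
               tolerance = 1e-12)
})

test_that("conductivity is monotone and bounded", {
  p <- fix("params")
  upper <- p$sigmaMax * (1 + p$Apg) * (1 + p$AT)
  set.seed(7)
  for (k in 1:100) {
    x <- c(runif(1), runif(1, 0, 1e-3), runif(1, 0, 5))
    s <- conductivity(x[1], x[2], x[3], p)
    expect_true(s >= p$sigma0 && s <= upper)
    # finite-difference monotonicity in each argument
    expect_gte(conductivity(min(x[1] + 1e-4, 1), x[2], x[3], p), s)
    expect_gte(conductivity(x[1], x[2] * 1.01 + 1e-9, x[3], p), s)
    expect_gte(conductivity(x[1], x[2], x[3] * 1.01 + 1e-9, p), s)
  }
})

test_that("capacitive density spikes at a step and decays with RC", {
  p <- fix("params")
  # steady state: no charging current
  r0 <- capacitive_current_density(500, 500, 1e-6, c(1, 0, 0), p)
  expect_equal(r0$magnitude, 0)
  # a 500 V step produces an initial spike of AC * dU / R
  dt <- p$R * p$C / 50
  r1 <- capacitive_current_density(500, 0, dt, c(1, 0, 0), p)
  expect_equal(r1$magnitude, p$AC * 500 / p$R * exp(-dt / (p$R * p$C)),
               tolerance = 1e-12)
  expect_equal(p$AC * 500 / p$R, 0.0167, tolerance = 5e-3)
  # log-magnitude of the step response decays with slope -1/(RC)
  mem <- 0
  mags <- times <- numeric(60)
  for (k in 1:60) {
    r <- capacitive_current_density(500, mem, dt, c(1, 0, 0), p)
    mem <- r$capMemory
    mags[k] <- r$magnitude
    times[k] <- k * dt
  }
  slope <- stats::coef(stats::lm(log(mags) ~ times))[2]
  expect_equal(unname(slope), -1 / (p$R * p$C), tolerance = 1e-2)
  # amplitude one RC after the step is e^-1 of the initial one
  kRC <- round(p$R * p$C / dt)
  expect_equal(mags[kRC] / mags[1], exp(-(kRC - 1) * dt / (p$R * p$C)),
               tolerance = 1e-9)
})

test_that("the state relaxes to virgin after a long rest", {
  p <- fix("params")
  # one 100 us pulse at 50 kV/m, then field-free rest of 10 * max(tau)
  pv <- update_poration(0, 5e4, 100e-6, p)
  dP <- update_damage(0, 5e4, 100e-6, TRUE, p$alphaP, p$tauRelax)
  dT <- update_damage(0, 5e4, 100e-6, TRUE, p$alphaT, p$tauT)
  rest <- 10 * max(p$tauRelax, p$tauPg, p$tauT)
  for (k in 1:10) {
    pv <- update_poration(pv, 0, rest / 10, p)
    dP <- update_damage(dP, 0, rest / 10, FALSE, p$alphaP, p$tauRelax)
    dT <- update_damage(dT, 0, rest / 10, FALSE, p$alphaT, p$tauT)
  }
  expect_lt(pv, 1e-3)
  expect_lt(dP, 1e-3)
  s <- conductivity(pv, dP, dT, p)
  expect_lt(abs(s - p$sigma0) / p$sigma0, 1e-3)
})
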