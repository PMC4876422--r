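test_that("pulse-train timing reproduces the delivered sequences", {
  # 100 us pulses with a 110 us minimum gap -> 4762 Hz repetition
  expect_equal(round(1 / (100e-6 + 110e-6)), 4762)
  s1 <- sequence_pulse_train(1)
  gap <- 1 / s1$repetitionFrequency - s1$pulseDuration
  expect_equal(gap, 110e-6, tolerance = 1e-3)
  # 8 x 1000 us at 1 Hz spans 7.001 s from first rise to last fall
  expect_equal(pulse_train_span(sequence_pulse_train(3)), 7.001)
  # single pulse: one trapezoid, zero outside
  tr <- pulse_train(500, 100e-6, 4762, pulseCount = 1)
  expect_equal(pulse_voltage(tr, c(-1e-6, 50e-6, 99e-6, 101e-6)),
               c(0, 500, 250, 0))
  expect_equal(pulse_voltage(tr, 1e-6), 250)  # mid-rise
  expect_error(pulse_train(500, 2e-3, 1000, 8), "overlap")
  expect_error(pulse_train(500, 1e-6, 1, 8, riseTime = 2e-6), "riseTime")
})

test_that("sampled trapezoid energy matches the closed form", {
  tr <- pulse_train(500, 100e-6, 4762, pulseCount = 2)
  smp <- make_pulse_train_trace(tr, 1e-7)
  energy <- sum(diff(smp$times) *
                  (smp$values[-1]^2 + smp$values[-length(smp$values)]^2) / 2)
  plateau <- tr$pulseDuration - tr$riseTime - tr$fallTime
  closed <- tr$pulseCount * 500^2 * (plateau + (tr$riseTime + tr$fallTime) / 3)
  expect_equal(energy, closed, tolerance = 1e-3)
})

test_that("trace files round-trip and reject malformed input", {
  tr <- make_pulse_train_trace(one_pulse(), 1e-6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f, kind = "voltage")
  expect_equal(back$times, tr$times, tolerance = 1e-12)
  expect_equal(back$values, tr$values, tolerance = 1e-12)
  expect_equal(back$meta$header, c("time", "voltage"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,U", "0,1", "1e-3,2", "1e-3,3", "2e-3,4"), f2)
  expect_error(read_trace(f2), "row 4")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1", "1e-3,NaN"), f3)
  expect_error(read_trace(f3), "NaN")
  expect_error(ep_trace(c(0, 1), c(1, 2, 3)), "equal length")
  expect_error(ep_trace(numeric(0), numeric(0)), "empty")
})

test_that("group down-sampling averages times and values, remainder included", {
  x <- ep_trace(seq_len(2000) * 1e-6, rep(c(1, 3), 1000), kind = "current")
  d <- downsample(x, 1000)
  expect_equal(length(d$times), 2)
  expect_equal(d$values, c(2, 2))
  expect_equal(d$times, c(mean(1:1000), mean(1001:2000)) * 1e-6)
  # identity at groupSize 1
  expect_equal(downsample(x, 1)$values, x$values)
  # 2500 samples -> 3 points, the last averaging 500 samples
  y <- ep_trace(seq_len(2500), seq_len(2500), kind = "current")
  d3 <- downsample(y, 1000)
  expect_equal(length(d3$times), 3)
  expect_equal(d3$values[3], mean(2001:2500))
})

test_that("replicate averaging aligns, averages and reports spread", {
  t0 <- seq(0, 1e-3, by = 1e-6)
  a <- ep_trace(t0, rep(1, length(t0)), kind = "current")
  b <- ep_trace(t0, rep(3, length(t0)), kind = "current")
  avg <- average_replicates(list(a, b))
  expect_equal(unique(avg$values), 2)
  five <- replicate(5, a, simplify = FALSE)
  same <- average_replicates(five)
  expect_equal(same$values, a$values)
  expect_equal(max(attr(same, "sd")), 0)
  # SD across n = 5 noisy replicates approximates the generating sigma
  set.seed(11)
  noisy <- lapply(1:5, function(i)
    ep_trace(t0, rnorm(length(t0), sd = 0.2), kind = "current"))
  sdHat <- mean(attr(average_replicates(noisy), "sd"))
  expect_lt(abs(sdHat - 0.2) / 0.2, 0.3)
  expect_error(average_replicates(list(a)), "at least 2")
  late <- ep_trace(t0 + 1, rep(1, length(t0)), kind = "current")
  expect_error(average_replicates(list(a, late)), "disjoint")
})

test_that("down-sampling commutes with replicate averaging on aligned grids", {
  t0 <- seq_len(4000) * 1e-7
  set.seed(3)
  a <- ep_trace(t0, rnorm(4000), kind = "current")
  b <- ep_trace(t0, rnorm(4000), kind = "current")
  left <- downsample(average_replicates(list(a, b)), 100)
  right <- average_replicates(list(downsample(a, 100), downsample(b, 100)))
  expect_equal(left$values, right$values, tolerance = 1e-12)
  expect_equal(left$times, right$times, tolerance = 1e-12)
})
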