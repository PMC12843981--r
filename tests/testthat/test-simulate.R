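test_that("with all noise off the trace is the quantised level", {
  cfg <- simulationConfig(duration = 0.01, samplingRate = 1e4,
                          states = list(stateSpec(0.125, 46, 0)),
                          rates = c(0, 0), measurementNoiseSigma = 0,
                          lsb = LSB, seed = 1)
  sim <- simulateTrace(cfg)
  expect_true(all(samples(sim$trace) == round(0.125 / LSB) * LSB))
})

test_that("identical seed and config give identical traces", {
  a <- telegraphTrace(7)
  b <- telegraphTrace(7)
  expect_identical(samples(a$trace), samples(b$trace))
  expect_identical(a$truth$switchTimes, b$truth$switchTimes)
})

test_that("RNG streams are independent: measurement noise does not perturb dwells", {
  mk <- function(noise) simulateTrace(simulationConfig(
    duration = 10, samplingRate = 1e4,
    states = list(stateSpec(0.110, 46, 0.005), stateSpec(0.140, 46, 0.005)),
    rates = c(1, 1), measurementNoiseSigma = noise, seed = 5))
  expect_identical(mk(0)$truth$switchTimes, mk(0.001)$truth$switchTimes)
})

test_that("all emitted samples are integer multiples of the LSB", {
  sim <- telegraphTrace(3, duration = 5)
  k <- samples(sim$trace) / LSB
  expect_lt(max(abs(k - round(k))), 1e-12 / LSB)
})

test_that("Markov occupancy converges to k21 / (k12 + k21)", {
  occ <- vapply(1:5, function(s) {
    sim <- simulateTrace(simulationConfig(
      duration = 100, samplingRate = 1e3,
      states = list(stateSpec(0.110, 46, 0.001), stateSpec(0.140, 46, 0.001)),
      rates = c(1, 1), seed = s))
    realizedOccupancy0(sim$truth, 100)
  }, numeric(1))
  expect_lt(max(abs(occ - 0.5)), 0.05 * sqrt(5))  # CLT-scale bound per seed
  expect_lt(abs(mean(occ) - 0.5), 0.05)
})

test_that("minDwell enforces a refractory separation between switches", {
  sim <- telegraphTrace(11, minDwell = 0.35)
  st <- sim$truth$switchTimes
  expect_true(length(st) > 2)
  expect_gte(min(diff(st)), 0.35)
})

test_that("the OU spectrum of a simulated trace matches the requested corner", {
  fits <- vapply(1:5, function(s) {
    sim <- ouTrace(seed = s, fc = 100, sigma = 0.0075, duration = 10,
                   fs = 2e4)
    x <- detrendVoltage(samples(sim$trace))
    cornerFreq(fitLorentzian(estimatePSD(x, 2e4)))
  }, numeric(1))
  expect_lt(abs(stats::median(fits) - 100) / 100, 0.05)
})

test_that("power series carries the linear corner-frequency law", {
  base <- simulationConfig(duration = 1, samplingRate = 1e4,
                           states = list(stateSpec(0.125, 46, 0.0075)),
                           rates = c(0, 0), seed = 2)
  series <- simulatePowerSeries(base, powers = c(6.8, 9, 11.3),
                                fcSlope = 0, fcIntercept = 40)
  fcs <- vapply(series, function(s)
    s$truth$config$states[[1]]$cornerFrequency, numeric(1))
  expect_equal(fcs, rep(40, 3))
  expect_equal(vapply(series, function(s) laserPower(s$trace), numeric(1)),
               c(6.8, 9, 11.3))
  expect_error(
    simulatePowerSeries(base, powers = 1, fcSlope = -1000,
                        fcIntercept = 5),
    "corner frequency <= 0")
})

test_that("a one-state config refuses nonzero switching rates", {
  expect_error(
    simulationConfig(states = list(stateSpec(0.125)), rates = c(1, 1)),
    "invalid for a 1-state")
})
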