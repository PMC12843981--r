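test_that("the low-pass filter has unit DC gain and strong stopband", {
  fs <- 2e4
  lp <- lowpassTrace(rep(0.125, fs), cutoff = 10, samplingRate = fs)
  expect_lt(max(abs(lp@samples - 0.125)), 1e-9)
  t <- (0:(2 * fs - 1)) / fs
  tone <- lowpassTrace(sin(2 * pi * 1000 * t), 10, samplingRate = fs)
  interior <- tone@samples[(fs %/% 2):(3 * fs %/% 2)]  # steady state
  atten <- sqrt(mean(interior^2)) / sqrt(0.5)
  expect_lt(20 * log10(atten), -40)
  expect_error(lowpassTrace(rnorm(100), 6e4, samplingRate = 1e5), "Nyquist")
})

test_that("a step-free noisy trace yields zero validated transitions", {
  sim <- ouTrace(seed = 8, fc = 46, sigma = 0.005, duration = 5, fs = 2e4)
  sq <- detectTransitions(lowpassTrace(sim$trace, 10))
  expect_identical(transitions(sq), integer(0))
  expect_length(segmentLevels(sq), 1L)
})

test_that("telegraph switches are validated accurately with few false positives", {
  stats <- sapply(1:5, function(s) {
    sim <- telegraphTrace(s)
    sq <- detectTransitions(lowpassTrace(sim$trace, 10))
    trueT <- sim$truth$switchTimes
    useful <- trueT > 0.3 & trueT < 20 - 0.3
    detT <- (transitions(sq) - 1) / 2e4
    hits <- vapply(trueT[useful], function(tt)
      any(abs(detT - tt) <= 0.05), logical(1))
    fp <- vapply(detT, function(dt)
      !any(abs(trueT - dt) <= 0.05), logical(1))
    c(nTrue = sum(useful), hit = sum(hits), nDet = length(detT),
      fp = sum(fp))
  })
  expect_gte(sum(stats["hit", ]) / sum(stats["nTrue", ]), 0.95)
  expect_lt(sum(stats["fp", ]) / max(1, sum(stats["nDet", ])), 0.05)
})

test_that("a 1 ms transient spike is rejected by the window rule", {
  sim <- ouTrace(seed = 3, fc = 46, sigma = 0.005, duration = 5, fs = 2e4)
  x <- samples(sim$trace)
  x[50000:50020] <- x[50000:50020] + 0.1
  sq <- detectTransitions(lowpassTrace(x, 10, samplingRate = 2e4))
  expect_identical(transitions(sq), integer(0))
})

test_that("detection is invariant to adding a constant", {
  sim <- telegraphTrace(4, duration = 10)
  a <- detectTransitions(lowpassTrace(sim$trace, 10))
  shifted <- samples(sim$trace) + 0.5
  b <- detectTransitions(lowpassTrace(shifted, 10, samplingRate = 2e4))
  expect_identical(transitions(a), transitions(b))
  expect_equal(segmentLevels(a), segmentLevels(b) - 0.5, tolerance = 1e-12)
})

test_that("disabling validation never decreases the transition count", {
  sim <- telegraphTrace(6, duration = 10)
  lp <- lowpassTrace(sim$trace, 10)
  strict <- detectTransitions(lp, levelFactor = 2)
  loose <- detectTransitions(lp, levelFactor = 0)
  expect_gte(length(transitions(loose)), length(transitions(strict)))
  expect_true(all(transitions(strict) %in% transitions(loose)))
})

test_that("occupancy follows segment durations exactly for clean levels", {
  fs <- 1000L
  x <- rep(c(0.110, 0.140, 0.110, 0.140), times = fs * c(1, 3, 1, 3))
  sq <- new("StateSequence",
            transitions = as.integer(cumsum(fs * c(1, 3, 1))) + 1L,
            segmentLevels = c(0.110, 0.140, 0.110, 0.140),
            labels = rep(NA_integer_, 4),
            occupancy = numeric(),
            dwellTimes = c(1, 3, 1, 3), samplingRate = fs,
            nSamples = length(x))
  lab <- assignStates(sq)
  expect_identical(stateLabels(lab), c(0L, 1L, 0L, 1L))
  expect_equal(unname(occupancy(lab)), c(0.25, 0.75), tolerance = 1e-12)
})

test_that("occupancy and dwell bookkeeping are consistent on telegraph data", {
  sim <- telegraphTrace(9, duration = 30)
  sq <- assignStates(detectTransitions(lowpassTrace(sim$trace, 10)))
  expect_equal(sum(occupancy(sq)), 1, tolerance = 1e-12)
  expect_equal(sum(dwellTimes(sq)), 30, tolerance = 2 / 2e4 * length(dwellTimes(sq)))
  occTrue <- realizedOccupancy0(sim$truth, 30)
  expect_lt(abs(unname(occupancy(sq)["0"]) - occTrue), 0.02)
})

test_that("a single segment maps to one state with occupancy 1", {
  sq <- new("StateSequence", transitions = integer(0),
            segmentLevels = 0.12, labels = NA_integer_,
            occupancy = numeric(), dwellTimes = 5, samplingRate = 1e4,
            nSamples = 50000L)
  lab <- assignStates(sq)
  expect_identical(stateLabels(lab), 0L)
  expect_equal(unname(occupancy(lab)), 1)
})

test_that("occupancy-vs-temperature table sorts, averages and flags ties", {
  mkseq <- function(occ0) {
    s <- new("StateSequence", transitions = 100L,
             segmentLevels = c(0.11, 0.14), labels = c(0L, 1L),
             occupancy = c("0" = occ0, "1" = 1 - occ0),
             dwellTimes = c(occ0, 1 - occ0) * 10, samplingRate = 1e3,
             nSamples = 10000L)
    s
  }
  tab <- occupancyVsTemperature(
    list(mkseq(0.6), mkseq(0.4), mkseq(0.5), mkseq(0.8)),
    temperatures = c(31, 30, 29, 31))
  expect_equal(tab$temperature, c(29, 30, 31))
  expect_equal(tab$occupancy0, c(0.5, 0.4, 0.7))
  expect_identical(tab$dominant, c("tie", "1", "0"))
  expect_equal(tab$nEntries, c(1L, 1L, 2L))
})
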