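test_that("CSV traces infer the sampling rate from the time column", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_s\tvoltage_v", "0\t0.1", "1e-05\t0.2", "2e-05\t0.3"), p)
  tr <- readTrace(p)
  expect_equal(samplingRate(tr), 1e5)
  expect_equal(samples(tr), c(0.1, 0.2, 0.3))
})

test_that("a bare voltage column without a sidecar is refused", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("voltage_v", "0.1", "0.2"), p)
  expect_error(readTrace(p), "sampling rate unavailable")
})

test_that("malformed time axes and non-finite samples are refused", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_s\tvoltage_v", "0\t0.1", "2e-05\t0.2", "1e-05\t0.3"), p)
  expect_error(readTrace(p), "strictly increasing")
  writeLines(c("time_s\tvoltage_v", "0\t0.1", "1e-05\t0.2", "5e-05\t0.3"), p)
  expect_error(readTrace(p), "non-uniform")
  writeLines(c("time_s\tvoltage_v", "0\t0.1", "1e-05\tNaN", "2e-05\t0.3"), p)
  expect_error(readTrace(p), "NaN")
})

test_that("binary round trip is bit-exact and preserves metadata", {
  sim <- ouTrace(seed = 42, duration = 10, fs = 1e5, power = 9)
  tr <- sim$trace
  p <- writeTrace(tr, withr::local_tempfile(), format = "f64")
  withr::defer(unlink(paste0(p, c("", ".json"))))
  back <- readTrace(p)
  expect_identical(samples(back), samples(tr))
  expect_identical(samplingRate(back), samplingRate(tr))
  expect_identical(laserPower(back), 9)
  expect_identical(lsb(back), lsb(tr))
})

test_that("float32 mode round-trips within float32 precision", {
  sim <- ouTrace(seed = 1, duration = 0.01, fs = 1e4)
  p <- writeTrace(sim$trace, withr::local_tempfile(), format = "f32")
  withr::defer(unlink(paste0(p, c("", ".json"))))
  back <- readTrace(p)
  expect_lt(max(abs(samples(back) - samples(sim$trace))), 1e-7)
})

test_that("degenerate traces cannot be constructed or written", {
  expect_error(TimeTrace(numeric(0)), "at least 2")
  expect_error(TimeTrace(c(0.1, NaN)), "finite")
  expect_error(TimeTrace(c(0.1, 0.2), samplingRate = 0), "positive")
})

test_that("trapping onset is located within 0.05 s across seeds", {
  errs <- vapply(1:20, function(s) {
    ev <- detectTrappingEvent(trapTrace(s))
    abs((onsetIndex(ev) - 1) / 2e4 - 2)
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("baseline statistics exclude post-onset samples", {
  ev <- detectTrappingEvent(trapTrace(3, jump = 0.05))
  # post-onset mean differs from baseline by 50x the baseline sd; a leak
  # of trapped samples into the baseline would drag the mean upward
  expect_lt(abs(ev@baselineMean - 0.05), 5e-4)
  expect_lt(ev@baselineStd, 0.002)
  expect_lt(onsetIndex(ev), ev@trappedStart)
})

test_that("traces without a qualifying jump raise 'no trapping event'", {
  set.seed(9)
  quiet <- TimeTrace(0.05 + rnorm(8e4) * 0.001, 2e4)
  expect_error(detectTrappingEvent(quiet), "no trapping event found")
})

test_that("a jump without a noise increase is rejected", {
  tr <- trapTrace(5, trappedSigma = 0.001)   # same noise level as baseline
  expect_error(detectTrappingEvent(tr), "noise increase")
})
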