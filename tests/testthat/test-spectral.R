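test_that("detrending annihilates lines and is idempotent", {
  t <- seq(0, 1, length.out = 1000)
  expect_lt(max(abs(detrendVoltage(0.3 + 2 * t))), 1e-12)
  expect_lt(max(abs(detrendVoltage(rep(0.125, 500)))), 1e-12)
  s <- sin(2 * pi * 7 * t)
  rec <- detrendVoltage(0.3 + 2 * t + s)
  expect_lt(sqrt(mean((rec - detrendVoltage(s))^2)), 1e-10)
  set.seed(1)
  x <- rnorm(1000)
  expect_lt(max(abs(detrendVoltage(detrendVoltage(x)) - detrendVoltage(x))),
            1e-12)
  expect_error(detrendVoltage(1), "at least 2")
})

test_that("Welch PSD satisfies Parseval on white noise", {
  set.seed(4)
  x <- rnorm(2e5)
  psd <- estimatePSD(x, 2e4)
  df <- psd@frequency[2] - psd@frequency[1]
  expect_lt(abs(sum(psd@density) * df - 1), 0.05)
})

test_that("Welch PSD locates a pure tone and handles degenerate input", {
  fs <- 2e4
  t <- (0:(10 * fs - 1)) / fs
  psd <- estimatePSD(sin(2 * pi * 1000 * t), fs)
  df <- psd@frequency[2] - psd@frequency[1]
  expect_lt(abs(psd@frequency[which.max(psd@density)] - 1000), df + 1e-9)
  z <- estimatePSD(rep(0, 2e4), fs)
  expect_true(all(z@density == 0))
  expect_error(estimatePSD(rnorm(100), fs), "shorter than one sub-segment")
})

test_that("an exact Lorentzian is recovered to numerical precision", {
  f <- 1:50000
  psd <- new("PSDEstimate", frequency = as.numeric(f),
             density = 1e-6 / (1 + (f / 50)^2), settings = list())
  fit <- fitLorentzian(psd, fitNoiseFloor = FALSE)
  expect_lt(abs(cornerFreq(fit) - 50), 1e-6)
  expect_lt(abs(plateau(fit) - 1e-6) / 1e-6, 1e-6)
})

test_that("the model at fc sits 3 dB below the plateau", {
  f <- 1:20000
  psd <- new("PSDEstimate", frequency = as.numeric(f),
             density = 2e-7 / (1 + (f / 120)^2) + 1e-11, settings = list())
  fit <- fitLorentzian(psd)
  expect_equal(lorentzianModel(fit, cornerFreq(fit)) - noiseFloor(fit),
               plateau(fit) / 2, tolerance = 1e-12)
})

test_that("fitted corner dispersion shrinks with segment length", {
  err <- function(dur) vapply(1:5, function(s) {
    sim <- ouTrace(seed = s, fc = 100, sigma = 0.0075, duration = dur,
                   fs = 2e4)
    x <- detrendVoltage(samples(sim$trace))
    abs(cornerFreq(fitLorentzian(estimatePSD(x, 2e4))) - 100)
  }, numeric(1))
  expect_lt(stats::median(err(10)), stats::median(err(2)) + 3)
  expect_lt(stats::median(err(10)) / 100, 0.05)
})

test_that("cornerFrequency equals the stepwise composition bit-for-bit", {
  tr <- trapOuTrace(21, fc = 46)
  ev <- detectTrappingEvent(tr)
  fs <- samplingRate(ev)
  seg <- trappedSamples(ev)[seq_len(round(10 * fs))]
  direct <- fitLorentzian(estimatePSD(detrendVoltage(seg), fs))
  expect_identical(cornerFrequency(ev), cornerFreq(direct))
  expect_lt(abs(cornerFrequency(ev) - 46) / 46, 0.2)  # single-seed estimate
})

test_that("segments shorter than the analysis window are refused", {
  tr <- trapOuTrace(22, trappedDuration = 3)
  ev <- detectTrappingEvent(tr)
  expect_error(cornerFrequency(ev, window = 10), "shorter than the analysis")
})
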