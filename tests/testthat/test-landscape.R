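test_that("laser power converts to local temperature linearly", {
  tm <- thermalModel(24)
  expect_equal(temperatureFromPower(tm, 0), 24)
  expect_equal(temperatureFromPower(tm, 11.3) - temperatureFromPower(tm, 6.8),
               2.61, tolerance = 1e-12)
  expect_equal(powerFromTemperature(tm, temperatureFromPower(tm, 7.7)), 7.7,
               tolerance = 1e-12)
  expect_error(temperatureFromPower(tm, -1), ">= 0")
})

test_that("the dithered density integrates to one and matches a known CDF", {
  set.seed(10)
  x <- 0.125 + rnorm(1e6) * 0.01
  est <- estimatePdf(x, landscapeConfig(seed = 2))
  bw <- est$binCenters[2] - est$binCenters[1]
  expect_lt(abs(sum(est$pdf) * bw - 1), 1e-9)
  # Kolmogorov distance between the binned empirical CDF and the truth
  ecdfv <- cumsum(est$pdf) * bw
  truth <- pnorm(est$binCenters + bw / 2, 0.125, sqrt(0.01^2 + LSB^2 / 12))
  expect_lt(max(abs(ecdfv - truth)), 0.005)
})

test_that("dithering removes the quantisation comb", {
  set.seed(11)
  raw <- c(0.110 + rnorm(5e4) * 0.004, 0.140 + rnorm(5e4) * 0.004)
  q <- round(raw / LSB) * LSB
  fine <- landscapeConfig(binWidth = LSB / 2, seed = 3)
  dith <- estimatePdf(q, fine)
  undith <- estimatePdf(q, landscapeConfig(binWidth = LSB / 2,
                                           ditherAmplitude = 0, seed = 3))
  support <- function(e) {
    occ <- which(e$pdf > 0)
    e$pdf[min(occ):max(occ)]
  }
  expect_true(any(support(undith) == 0))   # comb: empty bins inside support
  expect_false(any(support(dith) == 0))
})

test_that("Richardson-Lucy with a near-delta kernel is the identity", {
  centers <- seq(0.08, 0.17, by = LSB)
  p <- dnorm(centers, 0.125, 0.008)
  p <- p / (sum(p) * LSB)
  out <- deconvolvePdf(p, LSB / 10, LSB, 51)
  expect_lt(max(abs(out - p)), 1e-6)
})

test_that("Richardson-Lucy undoes a known Gaussian blur", {
  centers <- seq(0.06, 0.19, by = LSB)
  sigPsf <- 0.004; sigTrue <- 0.008
  obs <- dnorm(centers, 0.125, sqrt(sigTrue^2 + sigPsf^2))
  obs <- obs / (sum(obs) * LSB)
  dec <- deconvolvePdf(obs, sigPsf, LSB, 51)
  m <- sum(centers * dec) * LSB
  sdRec <- sqrt(sum((centers - m)^2 * dec) * LSB)
  expect_lt(abs(sdRec - sigTrue) / sigTrue, 0.10)
  expect_true(all(dec >= 0))
  expect_lt(abs(sum(dec) * LSB - 1), 1e-6)
})

test_that("Richardson-Lucy conserves mass at every iteration", {
  centers <- seq(0.08, 0.17, by = LSB)
  p <- 0.6 * dnorm(centers, 0.11, 0.006) + 0.4 * dnorm(centers, 0.14, 0.006)
  p <- p / (sum(p) * LSB)
  masses <- vapply(1:51, function(k)
    sum(deconvolvePdf(p, 0.005, LSB, k)) * LSB, numeric(1))
  expect_lt(max(abs(masses - 1)), 1e-6)
  expect_error(deconvolvePdf(p * 2, 0.005, LSB), "unit integral")
  expect_error(deconvolvePdf(p, LSB / 100, LSB), "at least")
})

test_that("Boltzmann inversion is exact and monotone", {
  expect_equal(boltzmannInvert(rep(2, 10)), rep(0, 10))
  u <- boltzmannInvert(c(1, exp(1)) / (1 + exp(1)), densityFloor = 0.01)
  expect_equal(u[1] - u[2], 1, tolerance = 1e-12)
  set.seed(12)
  p <- runif(50) + 0.1
  p <- p / sum(p)
  u <- boltzmannInvert(p)
  ord <- order(p)
  expect_true(all(diff(u[ord]) <= 1e-12))
})

test_that("minima extraction honours the sign convention and symmetry", {
  # grid symmetric about the midpoint so the two modes are sampled alike
  centers <- 0.125 + LSB * (-18:18)
  sym <- 0.5 * dnorm(centers, 0.11, 0.005) + 0.5 * dnorm(centers, 0.14, 0.005)
  sym <- sym / (sum(sym) * LSB)
  mm <- findMinimaDeltaG(centers, boltzmannInvert(sym))
  expect_lt(abs(mm$deltaG), 1e-9)
  # 0.7 weight at the LOWER voltage: lower minimum deeper, deltaG > 0
  mix <- 0.7 * dnorm(centers, 0.11, 0.005) + 0.3 * dnorm(centers, 0.14, 0.005)
  mix <- mix / (sum(mix) * LSB)
  mm2 <- findMinimaDeltaG(centers, boltzmannInvert(mix))
  expect_equal(mm2$deltaG, log(0.7 / 0.3), tolerance = 0.05 / 0.847)
  # same weights at swapped positions flips the sign
  swp <- 0.3 * dnorm(centers, 0.11, 0.005) + 0.7 * dnorm(centers, 0.14, 0.005)
  swp <- swp / (sum(swp) * LSB)
  mm3 <- findMinimaDeltaG(centers, boltzmannInvert(swp))
  expect_equal(mm3$deltaG, -log(0.7 / 0.3), tolerance = 0.05 / 0.847)
  # monotonic landscape has no pair of minima
  mono <- exp(seq(0, 3, length.out = 40))
  mono <- mono / sum(mono)
  expect_error(findMinimaDeltaG(seq_along(mono), boltzmannInvert(mono)),
               "single-state landscape")
})

test_that("quadratic stability fit recovers an exact vertex", {
  temps <- c(29.4, 29.9, 30.5, 31.0, 31.5)
  dg <- -0.35 * (temps - 30.4)^2 + 0.8
  sc <- fitStabilityCurve(temps, dg)
  expect_equal(vertexTemperature(sc), 30.4, tolerance = 1e-9)
  expect_true(sc@isMaximum)
  up <- fitStabilityCurve(temps, 0.2 * (temps - 30.4)^2)
  expect_false(up@isMaximum)
  expect_error(fitStabilityCurve(c(29, 30), c(0.1, 0.2)), "at least 3")
})

test_that("noisy stability curves recover the vertex within 0.3 degC", {
  temps <- c(29.4, 29.9, 30.5, 31.0, 31.5)
  set.seed(13)
  hits <- vapply(1:100, function(i) {
    dg <- -0.35 * (temps - 30.4)^2 + 0.8 + rnorm(5, sd = 0.05)
    abs(vertexTemperature(fitStabilityCurve(temps, dg)) - 30.4) <= 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("the landscape pipeline composes the stages and flags single states", {
  sim <- telegraphTrace(15, duration = 30, fs = 1e4, rates = c(1, 1),
                        minDwell = 0.35)
  fs <- 1e4
  set.seed(99)
  base <- 0.02 + rnorm(2 * fs) * 0.0008
  tr <- TimeTrace(c(round(base / LSB) * LSB, samples(sim$trace)), fs,
                  laserPower = 9)
  ev <- detectTrappingEvent(tr)
  sq <- assignStates(detectTransitions(lowpassTrace(
    trappedSamples(ev), 10, samplingRate = fs)))
  cfg <- landscapeConfig(psfSigma = 0.005, temperature = 300, seed = 4)
  land <- landscapePipeline(ev, sq, config = cfg)
  # stepwise reference
  est <- estimatePdf(trappedSamples(ev), cfg)
  dec <- deconvolvePdf(est$pdf, 0.005, cfg$binWidth, cfg$lrIterations)
  u <- boltzmannInvert(dec, cfg$densityFloor)
  expect_identical(land@pdfDeconvolved, dec)
  expect_identical(land@energy, u)
  expect_equal(nrow(land@minima), 2L)
  # single-state trace: no second minimum
  one <- trapOuTrace(16, fs = 1e4, sigma = 0.005)
  ev1 <- detectTrappingEvent(one)
  expect_warning(
    land1 <- landscapePipeline(ev1, NULL, config = cfg),
    "single-state")
  expect_true(is.na(deltaG(land1)))
})

test_that("end-to-end deltaG matches the log occupancy ratio", {
  sim <- simulateTrace(simulationConfig(
    duration = 100, samplingRate = 1e4,
    states = list(stateSpec(0.110, 46, 0.005), stateSpec(0.140, 46, 0.005)),
    rates = c(1, 1.5), seed = 11))
  x <- samples(sim$trace)
  est <- estimatePdf(x, landscapeConfig(seed = 5))
  dec <- deconvolvePdf(est$pdf, 0.005, LSB, 51)
  mm <- findMinimaDeltaG(est$binCenters, boltzmannInvert(dec))
  occ0 <- realizedOccupancy0(sim$truth, 100)
  expect_lt(abs(mm$deltaG - log(occ0 / (1 - occ0))), 0.15)
})
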