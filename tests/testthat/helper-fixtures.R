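# Shared fixture builders. Everything is generated in code at test time;
# sampling rates are chosen per test so the physics under test is preserved
# while the suite stays fast (the 10 Hz filter and tens-of-Hz corner
# frequencies are far below even a 10-20 kHz Nyquist).

LSB <- 0.002441

# single-state OU trace (no switching)
ouTrace <- function(seed, fc = 46, sigma = 0.0075, level = 0.125,
                    duration = 10, fs = 2e4, lsb = LSB, power = NA_real_) {
  simulateTrace(simulationConfig(
    duration = duration, samplingRate = fs,
    states = list(stateSpec(level, fc, sigma)),
    rates = c(0, 0), lsb = lsb, seed = seed, laserPower = power))
}

# telegraph trace with guaranteed minimum dwell (study condition for the
# step-detection criteria: gap >> 5x post-filter noise, dwell >= 0.3 s)
telegraphTrace <- function(seed, duration = 20, fs = 2e4,
                           levels = c(0.110, 0.140), fc = 46,
                           sigma = 0.005, rates = c(1.5, 1.5),
                           minDwell = 0.35, lsb = LSB) {
  simulateTrace(simulationConfig(
    duration = duration, samplingRate = fs,
    states = list(stateSpec(levels[1], fc, sigma),
                  stateSpec(levels[2], fc, sigma)),
    rates = rates, minDwell = minDwell, lsb = lsb, seed = seed))
}

# raw trace with a quiet baseline followed by a trapping jump at jumpAt
# seconds: step of `jump` volts plus white-noise increase
trapTrace <- function(seed, fs = 2e4, duration = 12, jumpAt = 2,
                      baseLevel = 0.05, baseSigma = 0.001,
                      jump = 0.01, trappedSigma = 0.003) {
  set.seed(seed)
  n <- round(duration * fs)
  x <- baseLevel + stats::rnorm(n) * baseSigma
  post <- (round(jumpAt * fs) + 1L):n
  extra <- sqrt(max(trappedSigma^2 - baseSigma^2, 0))
  x[post] <- x[post] + jump + stats::rnorm(length(post)) * extra
  TimeTrace(round(x / LSB) * LSB, fs)
}

# trapping trace whose trapped part is an OU process (for spectral tests)
trapOuTrace <- function(seed, fs = 2e4, fc = 46, sigma = 0.005,
                        level = 0.11, trappedDuration = 12,
                        power = NA_real_, label = list()) {
  set.seed(seed + 77777L)
  base <- 0.02 + stats::rnorm(round(2 * fs)) * 0.0008
  sim <- simulateTrace(simulationConfig(
    duration = trappedDuration, samplingRate = fs,
    states = list(stateSpec(0, fc, sigma)), rates = c(0, 0),
    lsb = 0, seed = seed))
  x <- c(base, level + samples(sim$trace))
  TimeTrace(round(x / LSB) * LSB, fs, laserPower = power, label = label)
}

# realized (ground-truth) occupancy of state 0 over the trace duration
realizedOccupancy0 <- function(truth, duration) {
  segs <- diff(c(0, truth$switchTimes, duration))
  sum(segs[truth$statePath == 0L]) / duration
}
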