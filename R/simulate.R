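# Synthetic NOT trace generator. Within each conformational state the
# transmitted-voltage fluctuation is an Ornstein-Uhlenbeck (OU) process
# whose one-sided power spectrum is Lorentzian with the requested corner
# frequency; two-state switching is a continuous-time Markov chain sampled
# exactly through its exponential dwell times. Laser (measurement) noise is
# additive white Gaussian, by default 20x smaller than the thermal
# fluctuation, and the output is quantised to the acquisition LSB.

#' Specify one conformational state of a simulated trace
#'
#' @param level mean transmitted voltage of the state (V).
#' @param cornerFrequency Lorentzian corner frequency of the within-state
#'   thermal fluctuation (Hz); the OU relaxation time is
#'   `1 / (2 * pi * cornerFrequency)`.
#' @param thermalSigma stationary standard deviation of the thermal
#'   fluctuation (V).
#' @return A list of class `StateSpec`.
#' @export
stateSpec <- function(level, cornerFrequency = 46, thermalSigma = 0.0075) {
  stopifnot(cornerFrequency > 0, thermalSigma >= 0)
  structure(list(level = level, cornerFrequency = cornerFrequency,
                 thermalSigma = thermalSigma), class = "StateSpec")
}

#' Configure a synthetic NOT trace
#'
#' Defaults reproduce the observable regime of a trapped ~76 kDa protein:
#' two transmission levels 0.110 and 0.140 V (mean 0.125 V, so a
#' single-state standard deviation of 6% of the mean is 0.0075 V),
#' second-scale Markov switching (both rates 1 Hz), 100 kHz sampling,
#' measurement noise 20 times smaller than the thermal fluctuation, and
#' quantisation at an LSB of 0.002441 V.
#'
#' @param duration trace length (s).
#' @param samplingRate sampling frequency (Hz).
#' @param states list of 1 or 2 [stateSpec()] objects.
#' @param rates two-state transition rates `c(k12, k21)` in Hz
#'   (state 1 -> 2, state 2 -> 1); ignored for a single state.
#' @param minDwell refractory time added to every dwell (s); dwells are
#'   `minDwell + Exp(rate)`. The default 0 gives a memoryless two-state
#'   Markov chain; a positive value produces telegraph signals whose
#'   switches are guaranteed to be separated by at least `minDwell`.
#' @param measurementNoiseSigma white measurement-noise sd (V); default
#'   `thermalSigma / 20` of the first state.
#' @param lsb quantisation step (V); 0 disables quantisation.
#' @param seed integer seed; identical seed and config give an identical
#'   trace. Internally split into independent streams for dwell times, OU
#'   noise, and measurement noise.
#' @param laserPower laser power recorded on the trace (mW).
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(duration = 10, samplingRate = 1e5,
                             states = list(stateSpec(0.110),
                                           stateSpec(0.140)),
                             rates = c(1, 1), minDwell = 0,
                             measurementNoiseSigma = NULL,
                             lsb = 0.002441, seed = 1,
                             laserPower = NA_real_) {
  stopifnot(duration > 0, duration * samplingRate >= 2,
            length(states) %in% 1:2, all(rates >= 0), minDwell >= 0,
            lsb >= 0)
  if (length(states) == 1L && any(rates > 0))
    stop("nonzero transition rates are invalid for a 1-state config")
  if (is.null(measurementNoiseSigma))
    measurementNoiseSigma <- states[[1]]$thermalSigma / 20
  stopifnot(measurementNoiseSigma >= 0)
  structure(list(duration = duration, samplingRate = samplingRate,
                 states = states, rates = rates, minDwell = minDwell,
                 measurementNoiseSigma = measurementNoiseSigma,
                 lsb = lsb, seed = as.integer(seed),
                 laserPower = laserPower),
            class = "SimulationConfig")
}

#' Simulate a NOT trapping trace with known ground truth
#'
#' The two-state path is a continuous-time Markov chain sampled exactly
#' (exponential dwells); switch times live on the continuous time axis and
#' are rounded to the nearest sample. Within state `i` the signal is
#' `level_i + x(t) + eta(t)` where `x` follows the exact OU discretisation
#' `x <- x * a + thermalSigma * sqrt(1 - a^2) * xi` with
#' `a = exp(-dt / tau_i)`, so the stationary statistics are exact at any
#' sampling rate. The OU coordinate is carried across switches (a
#' conformational change moves the scattering level, not the instantaneous
#' thermal coordinate). Samples are rounded to the nearest LSB multiple.
#'
#' @param config a [simulationConfig()].
#' @return A list with elements `trace` (a [TimeTrace-class]) and `truth`
#'   (a list: `switchTimes` in s, `statePath` of 0-based state indices per
#'   segment, `expectedOccupancy` of state 0 = `k21 / (k12 + k21)`, and the
#'   `config`).
#' @examples
#' sim <- simulateTrace(simulationConfig(duration = 1, samplingRate = 1e4))
#' sim$trace
#' @export
simulateTrace <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  fs <- config$samplingRate
  dt <- 1 / fs
  n <- round(config$duration * fs)
  set.seed(config$seed)
  subseeds <- sample.int(2^31 - 2, 3)

  nStates <- length(config$states)
  if (nStates == 1L) {
    switchTimes <- numeric()
    statePath <- 0L
    expOcc <- 1
  } else {
    k12 <- config$rates[1]
    k21 <- config$rates[2]
    m <- config$minDwell
    if (k12 + k21 > 0 && k12 > 0 && k21 > 0) {
      mean0 <- m + 1 / k12
      mean1 <- m + 1 / k21
      expOcc <- mean0 / (mean0 + mean1)   # = k21/(k12+k21) when m = 0
    } else expOcc <- 1
    set.seed(subseeds[1])
    s <- if (k12 + k21 == 0 || stats::runif(1) < expOcc) 0L else 1L
    tcur <- 0
    switchTimes <- numeric()
    statePath <- s
    repeat {
      rate <- if (s == 0L) k12 else k21
      if (rate <= 0) break
      tcur <- tcur + m + stats::rexp(1, rate)
      if (tcur >= config$duration) break
      switchTimes <- c(switchTimes, tcur)
      s <- 1L - s
      statePath <- c(statePath, s)
    }
  }

  # map switch times to segment boundaries (first sample of new segment)
  bnd <- round(switchTimes * fs) + 1L
  bnd <- pmin(pmax(bnd, 1L), n + 1L)
  segStart <- c(1L, bnd)
  segEnd <- c(bnd - 1L, n)
  segLen <- segEnd - segStart + 1L
  keep <- segLen > 0L
  segLen <- segLen[keep]
  segState <- statePath[keep]

  tau <- vapply(config$states, function(s) 1 / (2 * pi * s$cornerFrequency),
                numeric(1))
  sig <- vapply(config$states, function(s) s$thermalSigma, numeric(1))
  lev <- vapply(config$states, function(s) s$level, numeric(1))

  set.seed(subseeds[2])
  x <- numeric(n)
  xPrev <- stats::rnorm(1) * sig[segState[1] + 1L]
  pos <- 1L
  for (j in seq_along(segLen)) {
    st <- segState[j] + 1L
    a <- exp(-dt / tau[st])
    b <- sig[st] * sqrt(1 - a * a)
    innov <- stats::rnorm(segLen[j]) * b
    seg <- stats::filter(innov, a, method = "recursive", init = xPrev)
    seg <- as.numeric(seg)
    x[pos:(pos + segLen[j] - 1L)] <- seg
    xPrev <- seg[segLen[j]]
    pos <- pos + segLen[j]
  }

  set.seed(subseeds[3])
  eta <- if (config$measurementNoiseSigma > 0)
    stats::rnorm(n) * config$measurementNoiseSigma else numeric(n)

  y <- rep(lev[segState + 1L], segLen) + x + eta
  if (config$lsb > 0) y <- round(y / config$lsb) * config$lsb

  trace <- TimeTrace(y, samplingRate = fs, laserPower = config$laserPower,
                     lsb = if (config$lsb > 0) config$lsb else 0.002441,
                     label = list(source = "simulateTrace"))
  truth <- list(switchTimes = switchTimes, statePath = statePath,
                expectedOccupancy = expOcc, config = config)
  list(trace = trace, truth = truth)
}

#' Simulate a laser-power series for zero-power extrapolation
#'
#' Emulates corner-frequency spectroscopy across laser powers: at power `P`
#' the mean transmitted (APD) voltage is `levelPerMw * P` and the true
#' corner frequency is `fcIntercept + fcSlope * levelPerMw * P`, i.e.
#' linear in the APD voltage with a known zero-power intercept. Each trace
#' is single-state and carries `laserPower = P` so downstream
#' temperature conversion applies.
#'
#' @param base a [simulationConfig()] supplying duration, sampling rate,
#'   thermal sigma, noise, LSB, and the base seed (trace `i` uses
#'   `seed + i - 1`).
#' @param powers laser powers (mW).
#' @param fcSlope corner-frequency slope (Hz per V of APD voltage).
#' @param fcIntercept zero-power corner frequency (Hz).
#' @param levelPerMw APD voltage per mW of laser power (V/mW).
#' @return A list (one element per power) of `list(trace, truth)` as from
#'   [simulateTrace()].
#' @export
simulatePowerSeries <- function(base, powers, fcSlope, fcIntercept,
                                levelPerMw = 0.0125) {
  stopifnot(inherits(base, "SimulationConfig"), length(powers) >= 1)
  lapply(seq_along(powers), function(i) {
    P <- powers[i]
    level <- levelPerMw * P
    fc <- fcIntercept + fcSlope * level
    if (fc <= 0)
      stop("implied corner frequency <= 0 at power ", P, " mW")
    cfg <- simulationConfig(
      duration = base$duration, samplingRate = base$samplingRate,
      states = list(stateSpec(level, cornerFrequency = fc,
                              thermalSigma = base$states[[1]]$thermalSigma)),
      rates = c(0, 0),
      measurementNoiseSigma = base$measurementNoiseSigma,
      lsb = base$lsb, seed = base$seed + i - 1L, laserPower = P)
    simulateTrace(cfg)
  })
}
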