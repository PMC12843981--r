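# Free-energy landscape reconstruction: dither -> histogram -> Richardson-
# Lucy deconvolution of the thermal-motion PSF -> Boltzmann inversion
# U(V) = -kB T ln P(V), with deltaG read between the two local minima.

kBoltzmann <- 1.380649e-23  # J/K

#' Laser-heating thermal model
#'
#' The local temperature at the nanoaperture rises linearly with laser
#' power; the default heating coefficient for a 980 nm laser at a gold
#' double nanohole is 0.58 K/mW.
#'
#' @param ambientTemperature ambient (zero-power) temperature, degrees C.
#' @param heatingCoefficient K per mW of laser power (> 0).
#' @return A list of class `ThermalModel`.
#' @export
thermalModel <- function(ambientTemperature, heatingCoefficient = 0.58) {
  stopifnot(heatingCoefficient > 0, is.finite(ambientTemperature))
  structure(list(ambientTemperature = ambientTemperature,
                 heatingCoefficient = heatingCoefficient),
            class = "ThermalModel")
}

#' Local temperature at a given laser power
#'
#' @param model a [thermalModel()].
#' @param power laser power (mW, >= 0).
#' @return Local temperature in degrees C.
#' @export
temperatureFromPower <- function(model, power) {
  stopifnot(inherits(model, "ThermalModel"), all(power >= 0))
  model$ambientTemperature + model$heatingCoefficient * power
}

#' Laser power producing a given local temperature
#'
#' Inverse of [temperatureFromPower()].
#'
#' @param model a [thermalModel()].
#' @param temperature local temperature (degrees C).
#' @return Laser power in mW.
#' @export
powerFromTemperature <- function(model, temperature) {
  stopifnot(inherits(model, "ThermalModel"))
  (temperature - model$ambientTemperature) / model$heatingCoefficient
}

#' Configuration for free-energy landscape reconstruction
#'
#' @param binWidth histogram bin width (V); default one LSB — finer bins
#'   reintroduce the quantisation comb, coarser bins blur the two levels.
#' @param ditherAmplitude total width of the uniform dither noise (V);
#'   default one LSB.
#' @param psfSigma Gaussian PSF standard deviation (V); `NULL` means
#'   estimate from the longest single-state segment (thermal motion
#'   dominates it; the laser noise is ~20x smaller), with 6% of the
#'   segment mean as fallback.
#' @param lrIterations Richardson-Lucy iterations (default 51), run
#'   exactly, no early stopping.
#' @param temperature analysis temperature (K); `NULL` means derive from
#'   the trace laser power via a [thermalModel()].
#' @param densityFloor fraction of the peak density below which the
#'   energy is undefined (default 0.01).
#' @param seed seed for the dither noise.
#' @return A list of class `LandscapeConfig`.
#' @export
landscapeConfig <- function(binWidth = 0.002441, ditherAmplitude = 0.002441,
                            psfSigma = NULL, lrIterations = 51,
                            temperature = NULL, densityFloor = 0.01,
                            seed = 1) {
  stopifnot(binWidth > 0, ditherAmplitude >= 0, lrIterations >= 1,
            densityFloor > 0, densityFloor < 1)
  if (!is.null(psfSigma)) stopifnot(psfSigma > 0)
  structure(list(binWidth = binWidth, ditherAmplitude = ditherAmplitude,
                 psfSigma = psfSigma, lrIterations = as.integer(lrIterations),
                 temperature = temperature, densityFloor = densityFloor,
                 seed = as.integer(seed)),
            class = "LandscapeConfig")
}

#' Dithered probability density of a voltage segment
#'
#' Adds seeded uniform noise of total width `ditherAmplitude` (one LSB by
#' default) to every sample to eliminate digitisation artifacts, then
#' histograms with `binWidth` bins over the data range padded by 3 bins on
#' each side, normalised to unit integral.
#'
#' @param x voltage segment (>= 1e4 samples for a stable density).
#' @param config a [landscapeConfig()].
#' @return A list with `binCenters` (V) and `pdf` (1/V).
#' @export
estimatePdf <- function(x, config = landscapeConfig()) {
  stopifnot(inherits(config, "LandscapeConfig"))
  n <- length(x)
  if (n < 1e4) stop("need at least 1e4 samples for a stable density")
  if (diff(range(x)) <= 0) stop("zero dynamic range")
  set.seed(config$seed)
  A <- config$ditherAmplitude
  xd <- x + stats::runif(n, -A / 2, A / 2)
  bw <- config$binWidth
  lo <- min(xd) - 3 * bw
  breaks <- seq(lo, max(xd) + 4 * bw, by = bw)
  counts <- tabulate(findInterval(xd, breaks), nbins = length(breaks) - 1L)
  list(binCenters = breaks[-length(breaks)] + bw / 2,
       pdf = counts / (n * bw))
}

#' Richardson-Lucy deconvolution of a one-dimensional density
#'
#' Removes Gaussian broadening (here: thermal translational/rotational
#' motion in the trap) from a binned probability density by the standard
#' multiplicative Richardson-Lucy iteration. The transfer matrix is a
#' discretised Gaussian truncated at +/- 5 sigma with columns renormalised
#' to unit sum, which makes every iteration conserve total mass exactly
#' and preserve non-negativity. Exactly `iterations` iterations are run.
#'
#' @param pdf non-negative density on equally spaced bins, unit integral.
#' @param psfSigma Gaussian PSF sd (V); must be at least `binWidth / 10`.
#' @param binWidth bin spacing (V).
#' @param iterations iteration count (default 51).
#' @return The deconvolved density (1/V), same bins, unit integral.
#' @export
deconvolvePdf <- function(pdf, psfSigma, binWidth, iterations = 51) {
  stopifnot(all(pdf >= 0), iterations >= 1, binWidth > 0)
  if (psfSigma < binWidth / 10)
    stop("psfSigma must be at least binWidth / 10")
  mass <- sum(pdf) * binWidth
  if (abs(mass - 1) > 1e-6) stop("input density must have unit integral")
  nb <- length(pdf)
  half <- min(nb - 1L, ceiling(5 * psfSigma / binWidth))
  offsets <- (-half):half
  kern <- stats::dnorm(offsets * binWidth, sd = psfSigma)
  K <- matrix(0, nb, nb)
  for (j in seq_len(nb)) {
    ii <- j + offsets
    ok <- ii >= 1L & ii <= nb
    K[ii[ok], j] <- kern[ok]
  }
  K <- sweep(K, 2L, colSums(K), "/")   # column-stochastic: mass-exact RL
  eps <- 1e-12
  d <- pdf * binWidth
  u <- d
  for (it in seq_len(iterations)) {
    conv <- as.numeric(K %*% u)
    u <- u * as.numeric(crossprod(K, d / (conv + eps)))
  }
  u / binWidth
}

#' Boltzmann inversion of a probability density
#'
#' Converts an equilibrium density into free energy via
#' `U(V) = -kB T ln P(V)`, in kB*T units, on bins whose density exceeds
#' `densityFloor` times the peak (energies are unreliable where the
#' density is vanishing). The landscape is shifted so its minimum over the
#' defined domain is 0; undefined bins are `NA`.
#'
#' @param pdf non-negative density, unit integral.
#' @param densityFloor fraction of the peak density (default 0.01).
#' @return Energy per bin in kB*T units (`NA` below the floor).
#' @export
boltzmannInvert <- function(pdf, densityFloor = 0.01) {
  stopifnot(all(pdf >= 0), densityFloor > 0, densityFloor < 1)
  pk <- max(pdf)
  if (pk <= 0) stop("all bins below floor (empty density)")
  defined <- pdf > densityFloor * pk
  U <- rep(NA_real_, length(pdf))
  U[defined] <- -log(pdf[defined])
  U - min(U, na.rm = TRUE)
}

#' Energy in Joules
#'
#' Converts kB*T-unit energies to Joules at a given temperature.
#'
#' @param energyKbt energies in kB*T units.
#' @param temperature absolute temperature (K).
#' @return Energies in Joules.
#' @export
energyJoules <- function(energyKbt, temperature) {
  stopifnot(temperature > 0)
  energyKbt * kBoltzmann * temperature
}

#' Local minima and Gibbs free-energy difference of a landscape
#'
#' Local minima are defined bins strictly lower than both neighbours
#' (for a flat plateau the leftmost bin wins); if more than two exist the
#' two with lowest energy are kept. The Gibbs free-energy difference is
#' `deltaG = U(higher-voltage minimum) - U(lower-voltage minimum)`, so
#' `deltaG > 0` means the lower-voltage (compact) state is more stable.
#'
#' @param binCenters voltages (V).
#' @param energy energies in kB*T (`NA` where undefined); at least 5
#'   contiguous defined bins.
#' @return A list with `minima` (data.frame `voltage`, `energy`, ordered
#'   by voltage) and `deltaG` (kB*T). Errors with "single-state landscape"
#'   when fewer than 2 minima exist.
#' @export
findMinimaDeltaG <- function(binCenters, energy) {
  stopifnot(length(binCenters) == length(energy))
  def <- which(!is.na(energy))
  if (length(def) < 5L)
    stop("single-state landscape (energy defined on fewer than 5 bins)")
  mins <- integer()
  # scan each contiguous defined run with plateau-aware comparisons
  runs <- split(def, cumsum(c(1L, diff(def) > 1L)))
  for (run in runs) {
    if (length(run) < 3L) next
    u <- energy[run]
    r <- rle(u)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    if (length(r$values) < 3L) next
    for (k in 2:(length(r$values) - 1L)) {
      if (r$values[k] < r$values[k - 1L] && r$values[k] < r$values[k + 1L])
        mins <- c(mins, run[starts[k]])   # leftmost bin of the plateau
    }
  }
  if (length(mins) < 2L) stop("single-state landscape")
  if (length(mins) > 2L)
    mins <- mins[order(energy[mins])[1:2]]
  mins <- mins[order(binCenters[mins])]
  minima <- data.frame(voltage = binCenters[mins], energy = energy[mins])
  list(minima = minima, deltaG = minima$energy[2] - minima$energy[1])
}

#' Quadratic stability fit of deltaG versus temperature
#'
#' Least-squares fit of `deltaG(T) = a T^2 + b T + c`. The vertex
#' `-b / (2a)` is the temperature of extremal stability; with the sign
#' convention deltaG = U(high-V min) - U(low-V min), a concave fit
#' (`a < 0`) marks a stability maximum of the lower-voltage state.
#'
#' @param temperatures degrees C (>= 3 distinct values).
#' @param deltaGValues kB*T units.
#' @return A [StabilityCurve-class]; when `a == 0` the vertex is `NA`.
#' @export
fitStabilityCurve <- function(temperatures, deltaGValues) {
  stopifnot(length(temperatures) == length(deltaGValues))
  if (length(unique(temperatures)) < 3L)
    stop("need at least 3 distinct temperatures")
  fit <- stats::lm(deltaGValues ~ temperatures + I(temperatures^2))
  co <- stats::coef(fit)
  a <- unname(co[3]); b <- unname(co[2]); cc <- unname(co[1])
  vertex <- if (a != 0) -b / (2 * a) else NA_real_
  new("StabilityCurve",
      temperatures = temperatures, deltaGValues = deltaGValues,
      coefficients = c(a = a, b = b, c = cc),
      vertexTemperature = vertex, isMaximum = is.finite(a) && a < 0,
      residuals = unname(stats::residuals(fit)))
}

#' Full free-energy landscape of a trapping event
#'
#' Composition of [estimatePdf()], [deconvolvePdf()], [boltzmannInvert()]
#' and [findMinimaDeltaG()] on the trapped segment of an event. The PSF
#' sigma is taken from the configuration if set, otherwise estimated as
#' the standard deviation of the longest single-state stretch of the
#' supplied state sequence (dominated by thermal motion), falling back to
#' 6% of the segment mean. The analysis temperature comes from the
#' configuration or from the trace laser power via the thermal model.
#'
#' @param event a [TrappingEvent-class].
#' @param seq a labelled [StateSequence-class] computed on the trapped
#'   segment (used only for PSF estimation; may be `NULL` to force the 6%
#'   fallback).
#' @param thermal a [thermalModel()]; required when the configuration
#'   carries no explicit temperature.
#' @param config a [landscapeConfig()].
#' @return An [EnergyLandscape-class]. `deltaG` is `NA` (with a warning)
#'   for a single-state landscape.
#' @export
landscapePipeline <- function(event, seq = NULL, thermal = NULL,
                              config = landscapeConfig()) {
  stopifnot(is(event, "TrappingEvent"))
  x <- trappedSamples(event)
  tempK <- if (!is.null(config$temperature)) config$temperature else {
    if (is.null(thermal) || is.na(laserPower(event)))
      stop("need config$temperature or a thermal model + trace laser power")
    temperatureFromPower(thermal, laserPower(event)) + 273.15
  }
  psfSigma <- config$psfSigma
  psfSource <- "config"
  if (is.null(psfSigma)) {
    psfSigma <- longestSegmentSd(x, seq)
    psfSource <- "longest-single-state-segment"
    if (is.na(psfSigma)) {
      psfSigma <- 0.06 * abs(mean(x))
      psfSource <- "6%-of-mean-fallback"
    }
  }
  est <- estimatePdf(x, config)
  dec <- deconvolvePdf(est$pdf, psfSigma, config$binWidth,
                       config$lrIterations)
  U <- boltzmannInvert(dec, config$densityFloor)
  mm <- tryCatch(findMinimaDeltaG(est$binCenters, U),
                 error = function(e) {
                   warning(conditionMessage(e))
                   list(minima = data.frame(voltage = numeric(),
                                            energy = numeric()),
                        deltaG = NA_real_)
                 })
  new("EnergyLandscape",
      binCenters = est$binCenters, pdfRaw = est$pdf, pdfDeconvolved = dec,
      energy = U, minima = mm$minima, deltaG = mm$deltaG,
      temperature = tempK,
      parameters = list(binWidth = config$binWidth,
                        ditherAmplitude = config$ditherAmplitude,
                        psfSigma = psfSigma, psfSource = psfSource,
                        lrIterations = config$lrIterations,
                        densityFloor = config$densityFloor,
                        seed = config$seed))
}

# sd of the longest single-state segment; NA when no usable segment
longestSegmentSd <- function(x, seq) {
  if (is.null(seq) || !is(seq, "StateSequence")) return(NA_real_)
  starts <- c(1L, seq@transitions)
  ends <- c(seq@transitions - 1L, seq@nSamples)
  lens <- ends - starts + 1L
  j <- which.max(lens)
  if (lens[j] < 100L) return(NA_real_)
  stats::sd(x[starts[j]:min(ends[j], length(x))])
}
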