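#' @import methods
NULL

#' TimeTrace: a uniformly sampled transmitted-intensity time series
#'
#' Container for one avalanche-photodiode (APD) voltage trace recorded
#' through a nanoaperture optical tweezer. Time is implicit: sample `i`
#' (1-based) was taken at `(i - 1) / samplingRate` seconds. The data
#' acquisition quantises voltages to integer multiples of the least
#' significant bit (`lsb`).
#'
#' @slot samples numeric vector of voltages (V); finite, length >= 2.
#' @slot samplingRate sampling frequency in Hz (default 1e5).
#' @slot laserPower laser power in mW, or `NA` if unknown.
#' @slot lsb acquisition quantisation step in V (default 0.002441).
#' @slot label named list of free-text metadata.
#'
#' @export
setClass("TimeTrace",
  slots = c(
    samples      = "numeric",
    samplingRate = "numeric",
    laserPower   = "numeric",
    lsb          = "numeric",
    label        = "list"
  ),
  prototype = prototype(
    samplingRate = 1e5, laserPower = NA_real_, lsb = 0.002441,
    label = list()
  )
)

setValidity("TimeTrace", function(object) {
  msg <- character()
  if (length(object@samples) < 2L)
    msg <- c(msg, "trace must contain at least 2 samples")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite (no NaN/Inf)")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@lsb) != 1L || !is.finite(object@lsb) || object@lsb <= 0)
    msg <- c(msg, "lsb must be a single positive number")
  if (length(object@laserPower) != 1L)
    msg <- c(msg, "laserPower must be a single number (NA allowed)")
  if (length(msg)) msg else TRUE
})

#' Construct a TimeTrace
#'
#' @param samples numeric vector of voltages (V).
#' @param samplingRate sampling frequency in Hz.
#' @param laserPower laser power in mW (`NA` if unknown).
#' @param lsb quantisation step in V.
#' @param label named list of metadata.
#' @return A [TimeTrace-class] object.
#' @examples
#' tr <- TimeTrace(rnorm(100, 0.125, 0.005), samplingRate = 1e4)
#' duration(tr)
#' @export
TimeTrace <- function(samples, samplingRate = 1e5, laserPower = NA_real_,
                      lsb = 0.002441, label = list()) {
  new("TimeTrace", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate),
      laserPower = as.numeric(laserPower), lsb = as.numeric(lsb),
      label = label)
}

#' TrappingEvent: a located single-protein trapping event
#'
#' A trapping event is recognised by a sustained jump in transmitted laser
#' intensity accompanied by an increase in high-frequency noise from the
#' thermal motion of the trapped protein. Indices are 1-based and inclusive;
#' baseline statistics are computed strictly before `onsetIndex`.
#'
#' @slot trace the source [TimeTrace-class].
#' @slot onsetIndex first sample of the sustained jump.
#' @slot trappedStart first sample of the analysed trapped segment (after a
#'   settling guard that excludes the transition edge).
#' @slot trappedEnd last sample of the trapped segment.
#' @slot baselineMean mean pre-onset voltage (V).
#' @slot baselineStd standard deviation of pre-onset voltage (V).
#'
#' @export
setClass("TrappingEvent",
  slots = c(
    trace        = "TimeTrace",
    onsetIndex   = "integer",
    trappedStart = "integer",
    trappedEnd   = "integer",
    baselineMean = "numeric",
    baselineStd  = "numeric"
  )
)

setValidity("TrappingEvent", function(object) {
  n <- length(object@trace@samples)
  msg <- character()
  if (!(1L <= object@onsetIndex && object@onsetIndex < object@trappedStart))
    msg <- c(msg, "need 1 <= onsetIndex < trappedStart")
  if (!(object@trappedStart <= object@trappedEnd && object@trappedEnd <= n))
    msg <- c(msg, "need trappedStart <= trappedEnd <= trace length")
  if (length(msg)) msg else TRUE
})

#' FilteredTrace: a zero-phase low-pass filtered voltage signal
#'
#' @slot samples filtered voltages (V), same length as the input.
#' @slot raw the unfiltered input voltages (V); kept because transition
#'   validation measures local statistics on the raw signal.
#' @slot samplingRate sampling frequency (Hz).
#' @slot cutoff low-pass cutoff frequency (Hz).
#' @slot filterOrder Butterworth filter order.
#' @slot zeroPhase logical; TRUE for forward-backward application.
#' @export
setClass("FilteredTrace",
  slots = c(
    samples      = "numeric",
    raw          = "numeric",
    samplingRate = "numeric",
    cutoff       = "numeric",
    filterOrder  = "integer",
    zeroPhase    = "logical"
  )
)

setValidity("FilteredTrace", function(object) {
  if (object@cutoff >= object@samplingRate / 2)
    "cutoff must be below the Nyquist frequency" else TRUE
})

#' PSDEstimate: a one-sided averaged power spectral density
#'
#' @slot frequency frequencies in Hz, strictly increasing, excluding 0.
#' @slot density one-sided spectral density in V^2/Hz.
#' @slot settings list recording the estimator settings (segment length,
#'   sub-segment length, overlap, taper).
#' @export
setClass("PSDEstimate",
  slots = c(frequency = "numeric", density = "numeric", settings = "list")
)

setValidity("PSDEstimate", function(object) {
  msg <- character()
  if (length(object@frequency) != length(object@density))
    msg <- c(msg, "frequency and density lengths differ")
  if (any(diff(object@frequency) <= 0))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (length(object@frequency) && object@frequency[1] <= 0)
    msg <- c(msg, "frequencies must exclude 0")
  if (any(object@density < 0))
    msg <- c(msg, "density must be non-negative")
  if (length(msg)) msg else TRUE
})

#' LorentzianFit: corner-frequency fit of a power spectrum
#'
#' The fitted model is `S(f) = s0 / (1 + (f/fc)^2) + noiseFloor`; at the
#' corner frequency `fc` the Lorentzian term is reduced by 3 dB from its
#' low-frequency plateau `s0`.
#'
#' @slot s0 low-frequency plateau (V^2/Hz).
#' @slot fc corner frequency (Hz, > 0).
#' @slot noiseFloor additive white noise floor (V^2/Hz); 0 if not fitted.
#' @slot rss residual sum of squares in log10 space.
#' @slot band fitted frequency interval, `c(lo, hi)` in Hz.
#' @slot diagnostics list of fit diagnostics (points used, convergence).
#' @export
setClass("LorentzianFit",
  slots = c(
    s0 = "numeric", fc = "numeric", noiseFloor = "numeric",
    rss = "numeric", band = "numeric", diagnostics = "list"
  )
)

setValidity("LorentzianFit", function(object) {
  msg <- character()
  if (object@fc <= 0) msg <- c(msg, "fc must be positive")
  if (object@s0 < 0) msg <- c(msg, "s0 must be non-negative")
  if (object@noiseFloor < 0) msg <- c(msg, "noiseFloor must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ZeroPowerFit: linear extrapolation of corner frequency to zero power
#'
#' Ordinary least squares of corner frequency on transmitted power (APD
#' voltage or laser power). The intercept is the residual, zero-power corner
#' frequency attributable to electrostatic protein-surface interaction; a
#' negative intercept measures how much confining potential would be needed
#' to cancel a net repulsive interaction.
#'
#' @slot slope Hz per abscissa unit.
#' @slot intercept zero-power corner frequency (Hz); may be negative.
#' @slot stderrSlope standard error of the slope (`NA` with only 2 points).
#' @slot stderrIntercept standard error of the intercept.
#' @slot rSquared coefficient of determination.
#' @slot nPoints number of points fitted.
#' @slot abscissaKind `"apd_voltage_v"` or `"laser_power_mw"`.
#' @slot sampleLabel free-text sample description.
#' @export
setClass("ZeroPowerFit",
  slots = c(
    slope = "numeric", intercept = "numeric",
    stderrSlope = "numeric", stderrIntercept = "numeric",
    rSquared = "numeric", nPoints = "integer",
    abscissaKind = "character", sampleLabel = "character"
  )
)

#' StateSequence: validated two-state transitions of a trapped protein
#'
#' Transitions are sample indices (1-based, the first sample of the new
#' segment) validated by the step-height versus local-standard-deviation
#' rule. Labels are 0 for the lower-voltage state and 1 for the
#' higher-voltage state (`NA` before [assignStates()]).
#'
#' @slot transitions strictly increasing integer indices.
#' @slot segmentLevels mean voltage per inter-transition segment (V).
#' @slot labels integer 0/1 per segment (`NA` when unlabelled).
#' @slot occupancy named numeric, time fraction per label (sums to 1).
#' @slot dwellTimes seconds spent in each segment.
#' @slot samplingRate sampling frequency (Hz).
#' @slot nSamples number of samples in the analysed segment.
#' @export
setClass("StateSequence",
  slots = c(
    transitions = "integer", segmentLevels = "numeric",
    labels = "integer", occupancy = "numeric",
    dwellTimes = "numeric", samplingRate = "numeric", nSamples = "integer"
  )
)

setValidity("StateSequence", function(object) {
  msg <- character()
  if (length(object@transitions) && any(diff(object@transitions) <= 0))
    msg <- c(msg, "transitions must be strictly increasing")
  if (length(object@segmentLevels) != length(object@transitions) + 1L)
    msg <- c(msg, "number of segments must equal transitions + 1")
  if (length(object@occupancy) &&
      abs(sum(object@occupancy) - 1) > 1e-12)
    msg <- c(msg, "occupancies must sum to 1")
  if (length(msg)) msg else TRUE
})

#' EnergyLandscape: Gibbs free-energy landscape over transmitted voltage
#'
#' Built from a trapped-segment voltage distribution by dithering,
#' Richardson-Lucy deconvolution of the thermal-motion point spread
#' function, and Boltzmann inversion `U(V) = -kB T ln P(V)`. Energies are
#' in kB*T units, shifted so the global minimum is 0, and defined only
#' where the deconvolved density exceeds a floor fraction of its peak
#' (`NA` elsewhere).
#'
#' @slot binCenters voltage bin centers (V).
#' @slot pdfRaw dithered histogram density (1/V), unit integral.
#' @slot pdfDeconvolved deconvolved density (1/V), unit integral.
#' @slot energy U(V) in kB*T units (`NA` below the density floor).
#' @slot minima data.frame with columns `voltage`, `energy` for the
#'   retained local minima (at most 2, ordered by voltage).
#' @slot deltaG energy of the higher-voltage minimum minus the
#'   lower-voltage one (kB*T); positive when the lower-voltage state is
#'   more stable. `NA` for a single-state landscape.
#' @slot temperature analysis temperature (K).
#' @slot parameters list of all parameters used (bin width, dither
#'   amplitude, PSF sigma, iterations, density floor, seed).
#' @export
setClass("EnergyLandscape",
  slots = c(
    binCenters = "numeric", pdfRaw = "numeric", pdfDeconvolved = "numeric",
    energy = "numeric", minima = "data.frame", deltaG = "numeric",
    temperature = "numeric", parameters = "list"
  )
)

setValidity("EnergyLandscape", function(object) {
  msg <- character()
  nb <- length(object@binCenters)
  if (length(object@pdfRaw) != nb || length(object@pdfDeconvolved) != nb ||
      length(object@energy) != nb)
    msg <- c(msg, "pdf and energy vectors must match binCenters length")
  if (any(object@pdfDeconvolved < 0))
    msg <- c(msg, "deconvolved pdf must be non-negative")
  if (length(msg)) msg else TRUE
})

#' StabilityCurve: quadratic fit of Gibbs free-energy difference vs temperature
#'
#' Fits `deltaG(T) = a T^2 + b T + c` and reports the vertex temperature
#' `-b / (2 a)`. With the sign convention deltaG = U(higher-voltage
#' minimum) - U(lower-voltage minimum), a concave fit (`a < 0`) locates the
#' temperature of maximum stability of the lower-voltage state.
#'
#' @slot temperatures degrees Celsius.
#' @slot deltaGValues kB*T units.
#' @slot coefficients named numeric `c(a=, b=, c=)`.
#' @slot vertexTemperature `-b/(2a)` in degrees Celsius (`NA` if `a == 0`).
#' @slot isMaximum TRUE iff `a < 0`.
#' @slot residuals fit residuals (kB*T).
#' @export
setClass("StabilityCurve",
  slots = c(
    temperatures = "numeric", deltaGValues = "numeric",
    coefficients = "numeric", vertexTemperature = "numeric",
    isMaximum = "logical", residuals = "numeric"
  )
)
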