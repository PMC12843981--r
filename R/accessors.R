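#' @rdname TimeTrace-class
#' @export
setMethod("samples", "TimeTrace", function(object) object@samples)

#' @rdname TimeTrace-class
#' @export
setMethod("samplingRate", "TimeTrace", function(object) object@samplingRate)

#' @rdname TimeTrace-class
#' @export
setMethod("laserPower", "TimeTrace", function(object) object@laserPower)

#' @rdname TimeTrace-class
#' @export
setMethod("lsb", "TimeTrace", function(object) object@lsb)

#' @rdname TimeTrace-class
#' @export
setMethod("duration", "TimeTrace",
          function(object) length(object@samples) / object@samplingRate)

#' @rdname TimeTrace-class
#' @export
setMethod("length", "TimeTrace", function(x) length(x@samples))

#' @rdname TrappingEvent-class
#' @export
setMethod("onsetIndex", "TrappingEvent", function(object) object@onsetIndex)

#' @rdname TrappingEvent-class
#' @export
setMethod("trappedSpan", "TrappingEvent",
          function(object) c(object@trappedStart, object@trappedEnd))

#' @rdname TrappingEvent-class
#' @export
setMethod("trappedSamples", "TrappingEvent", function(object)
  object@trace@samples[object@trappedStart:object@trappedEnd])

#' @rdname TrappingEvent-class
#' @export
setMethod("samplingRate", "TrappingEvent",
          function(object) object@trace@samplingRate)

#' @rdname TrappingEvent-class
#' @export
setMethod("laserPower", "TrappingEvent",
          function(object) object@trace@laserPower)

#' @rdname LorentzianFit-class
#' @export
setMethod("cornerFreq", "LorentzianFit", function(object) object@fc)

#' @rdname LorentzianFit-class
#' @export
setMethod("plateau", "LorentzianFit", function(object) object@s0)

#' @rdname LorentzianFit-class
#' @export
setMethod("noiseFloor", "LorentzianFit", function(object) object@noiseFloor)

#' @rdname StateSequence-class
#' @export
setMethod("transitions", "StateSequence", function(object) object@transitions)

#' @rdname StateSequence-class
#' @export
setMethod("segmentLevels", "StateSequence",
          function(object) object@segmentLevels)

#' @rdname StateSequence-class
#' @export
setMethod("stateLabels", "StateSequence", function(object) object@labels)

#' @rdname StateSequence-class
#' @export
setMethod("occupancy", "StateSequence", function(object) object@occupancy)

#' @rdname StateSequence-class
#' @export
setMethod("dwellTimes", "StateSequence", function(object) object@dwellTimes)

#' @rdname EnergyLandscape-class
#' @export
setMethod("deltaG", "EnergyLandscape", function(object) object@deltaG)

#' @rdname EnergyLandscape-class
#' @export
setMethod("energyProfile", "EnergyLandscape", function(object)
  data.frame(voltage = object@binCenters, energy = object@energy))

#' @rdname StabilityCurve-class
#' @export
setMethod("vertexTemperature", "StabilityCurve",
          function(object) object@vertexTemperature)

setMethod("show", "TimeTrace", function(object) {
  cat(sprintf("TimeTrace: %d samples @ %g kHz (%.3f s)\n",
              length(object@samples), object@samplingRate / 1e3,
              duration(object)))
  cat(sprintf("  mean %.4f V, sd %.4f V, lsb %g V, laser power %s mW\n",
              mean(object@samples), stats::sd(object@samples), object@lsb,
              ifelse(is.na(object@laserPower), "NA",
                     format(object@laserPower))))
  if (length(object@label))
    cat("  label:", paste(names(object@label), unlist(object@label),
                          sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "TrappingEvent", function(object) {
  fs <- object@trace@samplingRate
  cat(sprintf(
    "TrappingEvent: onset %.3f s, trapped [%.3f, %.3f] s (%.2f s)\n",
    (object@onsetIndex - 1) / fs, (object@trappedStart - 1) / fs,
    (object@trappedEnd - 1) / fs,
    (object@trappedEnd - object@trappedStart + 1) / fs))
  cat(sprintf("  baseline %.4f +/- %.4f V\n",
              object@baselineMean, object@baselineStd))
  invisible(NULL)
})

setMethod("show", "LorentzianFit", function(object) {
  cat(sprintf(
    "LorentzianFit: fc = %.2f Hz, s0 = %.3g V^2/Hz, floor = %.3g V^2/Hz\n",
    object@fc, object@s0, object@noiseFloor))
  cat(sprintf("  band [%g, %g] Hz, log10 rss %.4g\n",
              object@band[1], object@band[2], object@rss))
  invisible(NULL)
})

setMethod("show", "ZeroPowerFit", function(object) {
  cat(sprintf(
    "ZeroPowerFit (%s%s): intercept %.2f +/- %s Hz, slope %.3g\n",
    object@abscissaKind,
    if (nzchar(object@sampleLabel)) paste0(", ", object@sampleLabel) else "",
    object@intercept,
    ifelse(is.na(object@stderrIntercept), "NA",
           sprintf("%.2f", object@stderrIntercept)),
    object@slope))
  cat(sprintf("  n = %d, R^2 = %.4f\n", object@nPoints, object@rSquared))
  invisible(NULL)
})

setMethod("show", "StateSequence", function(object) {
  cat(sprintf("StateSequence: %d validated transitions, %d segments\n",
              length(object@transitions), length(object@segmentLevels)))
  if (length(object@occupancy)) {
    occ <- paste(sprintf("state %s: %.3f", names(object@occupancy),
                         object@occupancy), collapse = ", ")
    cat(" ", occ, "\n")
  } else {
    cat("  (unlabelled; run assignStates())\n")
  }
  invisible(NULL)
})

setMethod("show", "EnergyLandscape", function(object) {
  cat(sprintf("EnergyLandscape: %d bins, T = %.2f K\n",
              length(object@binCenters), object@temperature))
  if (nrow(object@minima)) {
    for (i in seq_len(nrow(object@minima)))
      cat(sprintf("  minimum at %.4f V, U = %.3f kBT\n",
                  object@minima$voltage[i], object@minima$energy[i]))
  }
  cat(sprintf("  deltaG (high-V minus low-V minimum) = %s kBT\n",
              ifelse(is.na(object@deltaG), "NA",
                     sprintf("%.3f", object@deltaG))))
  invisible(NULL)
})

setMethod("show", "StabilityCurve", function(object) {
  co <- object@coefficients
  cat(sprintf("StabilityCurve: deltaG = %.4g T^2 + %.4g T + %.4g\n",
              co["a"], co["b"], co["c"]))
  cat(sprintf("  vertex at %.2f degC (%s)\n", object@vertexTemperature,
              if (isTRUE(object@isMaximum)) "stability maximum"
              else "no stability maximum"))
  invisible(NULL)
})
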