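#' @rdname TimeTrace-class
#' @param object,x an object.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname TimeTrace-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname TimeTrace-class
#' @export
setGeneric("laserPower", function(object) standardGeneric("laserPower"))

#' @rdname TimeTrace-class
#' @export
setGeneric("lsb", function(object) standardGeneric("lsb"))

#' @rdname TimeTrace-class
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @rdname TrappingEvent-class
#' @param object an object.
#' @export
setGeneric("onsetIndex", function(object) standardGeneric("onsetIndex"))

#' @rdname TrappingEvent-class
#' @export
setGeneric("trappedSpan", function(object) standardGeneric("trappedSpan"))

#' @rdname TrappingEvent-class
#' @export
setGeneric("trappedSamples",
           function(object) standardGeneric("trappedSamples"))

#' @rdname LorentzianFit-class
#' @param object an object.
#' @export
setGeneric("cornerFreq", function(object) standardGeneric("cornerFreq"))

#' @rdname LorentzianFit-class
#' @export
setGeneric("plateau", function(object) standardGeneric("plateau"))

#' @rdname LorentzianFit-class
#' @export
setGeneric("noiseFloor", function(object) standardGeneric("noiseFloor"))

#' @rdname StateSequence-class
#' @param object an object.
#' @export
setGeneric("transitions", function(object) standardGeneric("transitions"))

#' @rdname StateSequence-class
#' @export
setGeneric("segmentLevels",
           function(object) standardGeneric("segmentLevels"))

#' @rdname StateSequence-class
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))

#' @rdname StateSequence-class
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @rdname StateSequence-class
#' @export
setGeneric("dwellTimes", function(object) standardGeneric("dwellTimes"))

#' @rdname EnergyLandscape-class
#' @param object an object.
#' @export
setGeneric("deltaG", function(object) standardGeneric("deltaG"))

#' @rdname EnergyLandscape-class
#' @export
setGeneric("energyProfile", function(object) standardGeneric("energyProfile"))

#' @rdname StabilityCurve-class
#' @param object an object.
#' @export
setGeneric("vertexTemperature",
           function(object) standardGeneric("vertexTemperature"))
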