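#' Accessor generics
#'
#' Small accessor generics shared across the classes in this package.
#' Each data class documents which of these apply to it.
#'
#' @param x an object.
#' @return The slot value; see the class documentation for details.
#' @name accessors
#' @keywords internal
NULL

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("times", function(x) standardGeneric("times"))

#' @rdname accessors
#' @export
setGeneric("position", function(x) standardGeneric("position"))

#' @rdname accessors
#' @export
setGeneric("velocity", function(x) standardGeneric("velocity"))

#' @rdname accessors
#' @export
setGeneric("speed", function(x) standardGeneric("speed"))

#' @rdname accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))

#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setGeneric("validRows", function(x) standardGeneric("validRows"))

#' @rdname accessors
#' @export
setGeneric("lagCount", function(x) standardGeneric("lagCount"))

#' @rdname accessors
#' @export
setGeneric("filterWeights", function(x) standardGeneric("filterWeights"))

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @rdname accessors
#' @export
setGeneric("systemNoise", function(x) standardGeneric("systemNoise"))

#' @rdname accessors
#' @export
setGeneric("observationMatrix", function(x) standardGeneric("observationMatrix"))

#' @rdname accessors
#' @export
setGeneric("observationNoise", function(x) standardGeneric("observationNoise"))

#' @rdname accessors
#' @export
setGeneric("stateDim", function(x) standardGeneric("stateDim"))

#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("stateCovariances", function(x) standardGeneric("stateCovariances"))

#' @rdname accessors
#' @export
setGeneric("speedScale", function(x) standardGeneric("speedScale"))

#' @rdname accessors
#' @export
setGeneric("reachMask", function(x) standardGeneric("reachMask"))

#' @rdname accessors
#' @export
setGeneric("trialEvents", function(x) standardGeneric("trialEvents"))

#' @rdname accessors
#' @export
setGeneric("benchmarkSummary", function(x) standardGeneric("benchmarkSummary"))

#' @rdname accessors
#' @export
setGeneric("perTrialMetrics", function(x) standardGeneric("perTrialMetrics"))

#' @rdname accessors
#' @export
setGeneric("decoderComparisons", function(x) standardGeneric("decoderComparisons"))
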