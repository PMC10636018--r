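#' Accessors for laminar data objects
#'
#' @param object a \linkS4class{LaminarLFP}, \linkS4class{SpikeUnit},
#'   \linkS4class{UnitMetrics} or \linkS4class{EntrainmentProfile}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lfpData", function(object) standardGeneric("lfpData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("layers", function(object) standardGeneric("layers"))
#' @rdname accessors
#' @export
setGeneric("oscillators", function(object) standardGeneric("oscillators"))
#' @rdname accessors
#' @export
setGeneric("eventLog", function(object) standardGeneric("eventLog"))
#' @rdname accessors
#' @export
setGeneric("recordingDuration",
           function(object) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("unitId", function(object) standardGeneric("unitId"))
#' @rdname accessors
#' @export
setGeneric("maxChannel", function(object) standardGeneric("maxChannel"))
#' @rdname accessors
#' @export
setGeneric("unitLayer", function(object) standardGeneric("unitLayer"))
#' @rdname accessors
#' @export
setGeneric("unitGroup", function(object) standardGeneric("unitGroup"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("waveform", function(object) standardGeneric("waveform"))

#' @rdname accessors
#' @export
setMethod("lfpData", "LaminarLFP", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("samplingRate", "LaminarLFP", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("nChannels", "LaminarLFP", function(object) nrow(object@data))
#' @rdname accessors
#' @export
setMethod("layers", "LaminarLFP", function(object) object@layers)
#' @rdname accessors
#' @export
setMethod("oscillators", "LaminarLFP", function(object) object@oscillators)
#' @rdname accessors
#' @export
setMethod("eventLog", "LaminarLFP", function(object) object@events)
#' @rdname accessors
#' @export
setMethod("recordingDuration", "LaminarLFP",
          function(object) ncol(object@data) / object@samplingRate)

#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeUnit", function(object) object@spikeTimes)
#' @rdname accessors
#' @export
setMethod("unitId", "SpikeUnit", function(object) object@unitId)
#' @rdname accessors
#' @export
setMethod("maxChannel", "SpikeUnit", function(object) object@maxChannel)
#' @rdname accessors
#' @export
setMethod("unitLayer", "SpikeUnit", function(object) object@layer)
#' @rdname accessors
#' @export
setMethod("unitGroup", "SpikeUnit", function(object) object@group)
#' @rdname accessors
#' @export
setMethod("groundTruth", "SpikeUnit", function(object) object@groundTruth)
#' @rdname accessors
#' @export
setMethod("waveform", "SpikeUnit", function(object)
  data.frame(time_ms = object@waveformTime, uv = object@waveformUv))
#' @rdname accessors
#' @export
setMethod("unitId", "UnitMetrics", function(object) object@unitId)
#' @rdname accessors
#' @export
setMethod("unitId", "EntrainmentProfile", function(object) object@unitId)
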