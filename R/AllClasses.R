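#' @import methods
NULL

setClassUnion("dataFrameOrNULL", c("data.frame", "NULL"))

#' LaminarLFP: multichannel laminar field-potential recording
#'
#' Channels x samples potential matrix (microvolt) with sampling rate,
#' inter-channel spacing and a per-channel layer annotation
#' (\code{"ca1_pyr"}, \code{"below_pyr"} or \code{"unknown"}). Synthetic
#' recordings additionally carry the generating oscillator table (used as
#' analytic ground-truth phase) and a ground-truth event log.
#'
#' @slot data numeric matrix, channels x samples, microvolt.
#' @slot samplingRate sampling rate in Hz.
#' @slot spacing inter-channel spacing in micrometres.
#' @slot layers character vector, one layer label per channel.
#' @slot oscillators data.frame of generating oscillators (freq, amplitude,
#'   phi0, centerChannel, widthChannels) or NULL for real data.
#' @slot events data.frame ground-truth event log (type, onset, duration,
#'   amplitude, freq, channelFraction) or NULL.
#' @slot group group label, e.g. "control" or "post_mtbi".
#' @slot animalId animal identifier.
#' @export
setClass("LaminarLFP",
  representation(data = "matrix", samplingRate = "numeric",
                 spacing = "numeric", layers = "character",
                 oscillators = "dataFrameOrNULL", events = "dataFrameOrNULL",
                 group = "character", animalId = "character"),
  prototype(spacing = 100, oscillators = NULL, events = NULL,
            group = "control", animalId = "animal01"))

setValidity("LaminarLFP", function(object) {
  msg <- NULL
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (length(object@layers) != nrow(object@data))
    msg <- c(msg, "one layer label per channel required")
  if (!all(object@layers %in% c("ca1_pyr", "below_pyr", "unknown")))
    msg <- c(msg, "layers must be ca1_pyr, below_pyr or unknown")
  if (is.null(msg)) TRUE else msg
})

#' SpikeUnit: one sorted single unit
#'
#' Spike times (seconds, strictly increasing), the mean extracellular
#' waveform sampled around the spike, the channel of maximal amplitude and
#' animal/group metadata. Synthetic units also carry their generating ground
#' truth.
#'
#' @slot unitId unit identifier.
#' @slot spikeTimes numeric, seconds, strictly increasing.
#' @slot waveformTime numeric, milliseconds relative to window start.
#' @slot waveformUv numeric, microvolt, same length as waveformTime.
#' @slot maxChannel integer channel index of maximal spike amplitude.
#' @slot layer layer label of that channel.
#' @slot animalId,group metadata labels.
#' @slot groundTruth list of generator parameters (synthetic units) or empty.
#' @export
setClass("SpikeUnit",
  representation(unitId = "character", spikeTimes = "numeric",
                 waveformTime = "numeric", waveformUv = "numeric",
                 maxChannel = "integer", layer = "character",
                 animalId = "character", group = "character",
                 groundTruth = "list"),
  prototype(layer = "unknown", animalId = "animal01", group = "control",
            groundTruth = list()))

setValidity("SpikeUnit", function(object) {
  msg <- NULL
  st <- object@spikeTimes
  if (length(st) && (is.unsorted(st, strictly = TRUE) || any(st < 0)))
    msg <- c(msg, "spikeTimes must be non-negative and strictly increasing")
  if (length(object@waveformTime) != length(object@waveformUv))
    msg <- c(msg, "waveform time and voltage must have equal length")
  if (length(object@waveformTime) >= 2) {
    if (length(object@waveformTime) < 16 ||
        diff(range(object@waveformTime)) < 1)
      msg <- c(msg, "waveform must have >= 16 samples spanning >= 1 ms")
  }
  if (is.null(msg)) TRUE else msg
})

#' UnitMetrics: per-unit electrophysiological metrics
#'
#' @slot unitId unit identifier.
#' @slot firingRate Hz.
#' @slot spikeAmplitude microvolt, baseline-to-peak.
#' @slot spikeWidth ms at half amplitude.
#' @slot acg autocorrelogram probability per 1-ms lag, lags 1-50 ms.
#' @slot acgFirstMoment probability-weighted mean lag, ms.
#' @slot layer,animalId,group metadata carried through from the unit.
#' @export
setClass("UnitMetrics",
  representation(unitId = "character", firingRate = "numeric",
                 spikeAmplitude = "numeric", spikeWidth = "numeric",
                 acg = "numeric", acgFirstMoment = "numeric",
                 layer = "character", animalId = "character",
                 group = "character"))

setValidity("UnitMetrics", function(object) {
  msg <- NULL
  if (length(object@acg) != 50) msg <- c(msg, "acg must have 50 lags (1-50 ms)")
  if (any(object@acg < 0)) msg <- c(msg, "acg entries must be >= 0")
  s <- sum(object@acg)
  if (s > 0 && abs(s - 1) > 1e-8) msg <- c(msg, "non-empty acg must sum to 1")
  if (!is.na(object@acgFirstMoment) &&
      (object@acgFirstMoment < 1 || object@acgFirstMoment > 50))
    msg <- c(msg, "acgFirstMoment must lie in [1, 50] ms")
  if (is.null(msg)) TRUE else msg
})

#' EntrainmentProfile: per-band spike-LFP mean vector length for one unit
#'
#' @slot unitId unit identifier.
#' @slot bandLow,bandHigh band edges, Hz.
#' @slot mvl mean vector length per band, in [0, 1] (NA where no spikes
#'   survived edge trimming).
#' @slot nSpikes spikes entering each band's phase pool.
#' @export
setClass("EntrainmentProfile",
  representation(unitId = "character", bandLow = "numeric",
                 bandHigh = "numeric", mvl = "numeric", nSpikes = "integer"))

setValidity("EntrainmentProfile", function(object) {
  msg <- NULL
  n <- length(object@bandLow)
  if (length(object@bandHigh) != n || length(object@mvl) != n ||
      length(object@nSpikes) != n)
    msg <- c(msg, "band edges, mvl and nSpikes must have equal length")
  if (any(object@bandHigh <= object@bandLow))
    msg <- c(msg, "bands must have positive width")
  ok <- !is.na(object@mvl)
  if (any(object@mvl[ok] < 0 | object@mvl[ok] > 1))
    msg <- c(msg, "mvl must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LaminarLFP", function(object) {
  cat("LaminarLFP:", nrow(object@data), "channels x", ncol(object@data),
      "samples @", object@samplingRate, "Hz (",
      round(ncol(object@data) / object@samplingRate, 2), "s )\n")
  cat("  spacing:", object@spacing, "um; group:", object@group,
      "; animal:", object@animalId, "\n")
  cat("  layers:", paste(rle(object@layers)$values, collapse = " | "), "\n")
  if (!is.null(object@oscillators) && nrow(object@oscillators))
    cat("  oscillators at", paste(object@oscillators$freq, collapse = ", "),
        "Hz\n")
  if (!is.null(object@events) && nrow(object@events))
    cat("  ground-truth events:", nrow(object@events), "\n")
})

setMethod("show", "SpikeUnit", function(object) {
  cat("SpikeUnit", object@unitId, "(", object@group, "/", object@animalId,
      "):", length(object@spikeTimes), "spikes, max channel",
      object@maxChannel, "in layer", object@layer, "\n")
})

setMethod("show", "UnitMetrics", function(object) {
  cat(sprintf(
    "UnitMetrics %s: rate %.3g Hz, amplitude %.4g uV, width %.3g ms, ACG 1st moment %.3g ms\n",
    object@unitId, object@firingRate, object@spikeAmplitude,
    object@spikeWidth, object@acgFirstMoment))
})

setMethod("show", "EntrainmentProfile", function(object) {
  best <- which.max(object@mvl)
  cat("EntrainmentProfile", object@unitId, ":", length(object@mvl), "bands;")
  if (length(best))
    cat(sprintf(" peak MVL %.4g in %g-%g Hz", object@mvl[best],
                object@bandLow[best], object@bandHigh[best]))
  cat("\n")
})
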