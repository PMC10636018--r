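## File interchange: LFP as raw little-endian float32 channel-major binary
## with a JSON sidecar, spike times / waveforms / metrics as CSV.

#' Write an LFP to binary + JSON sidecar
#'
#' Channel-major (channel 1's full trace, then channel 2's, ...) 32-bit
#' little-endian floats, with sampling rate, geometry and layer labels in a
#' JSON sidecar next to the binary.
#'
#' @param lfp a \linkS4class{LaminarLFP}.
#' @param path path of the binary file; the sidecar is \code{<path>.json}.
#' @return invisibly, the two paths.
#' @export
writeLFP <- function(lfp, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(lfpData(lfp))), con, size = 4, endian = "little")
  sidecar <- list(samplingRate = samplingRate(lfp),
                  nChannels = nChannels(lfp),
                  nSamples = ncol(lfpData(lfp)),
                  spacing_um = lfp@spacing, layers = layers(lfp),
                  group = lfp@group, animalId = lfp@animalId)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(path, paste0(path, ".json")))
}

#' Read an LFP written by \code{\link{writeLFP}}
#'
#' @param path path of the binary file (sidecar expected at
#'   \code{<path>.json}).
#' @return a \linkS4class{LaminarLFP} (without synthetic ground truth).
#' @export
readLFP <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = meta$nChannels * meta$nSamples,
               size = 4, endian = "little")
  new("LaminarLFP",
      data = matrix(x, nrow = meta$nChannels, byrow = TRUE),
      samplingRate = meta$samplingRate, spacing = meta$spacing_um,
      layers = meta$layers, oscillators = NULL, events = NULL,
      group = meta$group, animalId = meta$animalId)
}

#' Write spike times of a unit list to CSV
#'
#' Long format: one row per spike (unit_id, time_s).
#'
#' @param units list of \linkS4class{SpikeUnit}.
#' @param path CSV path.
#' @export
writeSpikesCsv <- function(units, path) {
  rows <- do.call(rbind, lapply(units, function(u)
    data.frame(unit_id = unitId(u), time_s = spikeTimes(u))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write mean waveforms of a unit list to CSV
#'
#' Long format: one row per sample (unit_id, sample_ms, uv).
#'
#' @inheritParams writeSpikesCsv
#' @export
writeWaveformsCsv <- function(units, path) {
  rows <- do.call(rbind, lapply(units, function(u) {
    wf <- waveform(u)
    data.frame(unit_id = unitId(u), sample_ms = wf$time_ms, uv = wf$uv)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read spike-time and waveform CSVs back into units
#'
#' Metadata (channel, layer, group) defaults to unknown; supply a
#' \code{meta} data.frame (unit_id, max_channel, layer, animal_id, group) to
#' restore it.
#'
#' @param spikesPath CSV from \code{\link{writeSpikesCsv}}.
#' @param waveformsPath CSV from \code{\link{writeWaveformsCsv}}.
#' @param meta optional metadata data.frame.
#' @return list of \linkS4class{SpikeUnit}.
#' @export
readUnitsCsv <- function(spikesPath, waveformsPath, meta = NULL) {
  sp <- utils::read.csv(spikesPath)
  wf <- utils::read.csv(waveformsPath)
  ids <- unique(sp$unit_id)
  lapply(ids, function(id) {
    w <- wf[wf$unit_id == id, ]
    m <- if (!is.null(meta)) meta[meta$unit_id == id, ] else NULL
    new("SpikeUnit", unitId = as.character(id),
        spikeTimes = sort(sp$time_s[sp$unit_id == id]),
        waveformTime = w$sample_ms, waveformUv = w$uv,
        maxChannel = if (!is.null(m) && nrow(m)) as.integer(m$max_channel)
                     else NA_integer_,
        layer = if (!is.null(m) && nrow(m)) m$layer else "unknown",
        animalId = if (!is.null(m) && nrow(m)) m$animal_id else "unknown",
        group = if (!is.null(m) && nrow(m)) m$group else "unknown")
  })
}

#' Write a unit metrics table to CSV
#'
#' @param metrics data.frame from \code{\link{unitMetricsTable}}.
#' @param path CSV path.
#' @export
writeMetricsCsv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
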