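## Per-unit electrophysiological metrics: firing rate, spike autocorrelogram
## (1 ms bins, lags 1-50 ms, normalized to a probability distribution) and
## its first moment, baseline-to-peak spike amplitude and width at half
## amplitude. These definitions are shared with the biophysical model so the
## factor semantics match between experiment-like and simulated waveforms.

#' Mean firing rate
#'
#' Average number of spikes per second over the recording.
#'
#' @param unit a \linkS4class{SpikeUnit} (or numeric spike times, seconds).
#' @param duration recording duration, seconds (> 0).
#' @return rate in Hz. A unit with zero spikes returns 0 with a warning:
#'   such units should have been excluded upstream.
#' @export
firingRate <- function(unit, duration) {
  if (duration <= 0) stop("duration must be > 0")
  st <- if (is(unit, "SpikeUnit")) spikeTimes(unit) else unit
  if (length(st) == 0) {
    warning("unit has zero spikes; returning 0 Hz")
    return(0)
  }
  length(st) / duration
}

#' Spike autocorrelogram over 1-50 ms lags
#'
#' For each lag l in 1..50 ms, counts ordered spike pairs whose time
#' difference falls in (l - 0.5, l + 0.5] ms, then divides by the total count
#' over all lags so that the result is a probability distribution (all zeros
#' if no pair is within 50 ms).
#'
#' @param unit a \linkS4class{SpikeUnit} or numeric spike times in seconds
#'   (>= 2 spikes).
#' @return numeric(50), probability per 1-ms lag.
#' @export
spikeAutocorrelogram <- function(unit) {
  st <- if (is(unit, "SpikeUnit")) spikeTimes(unit) else unit
  n <- length(st)
  if (n < 2) stop("autocorrelogram needs at least 2 spikes")
  counts <- numeric(50)
  for (i in seq_len(n - 1)) {
    k <- i + 1L
    while (k <= n) {
      dms <- (st[k] - st[i]) * 1000
      if (dms > 50.5) break
      lag <- ceiling(dms - 0.5)           # (l - 0.5, l + 0.5] binning
      if (lag >= 1) counts[lag] <- counts[lag] + 1
      k <- k + 1L
    }
  }
  tot <- sum(counts)
  if (tot > 0) counts / tot else counts
}

#' First moment of the autocorrelogram
#'
#' Probability-weighted mean lag, \code{sum(l * acg[l])} over lags 1-50 ms.
#' Small for bursty firing, large for tonic firing.
#'
#' @param acg normalized autocorrelogram from
#'   \code{\link{spikeAutocorrelogram}}.
#' @return mean lag in ms, or NA (with a warning) for an all-zero acg.
#' @export
acgFirstMoment <- function(acg) {
  if (sum(acg) == 0) {
    warning("all-zero autocorrelogram: first moment undefined")
    return(NA_real_)
  }
  sum(seq_along(acg) * acg)
}

waveformBaseline <- function(uv) {
  ## baseline = mean of the first quarter of the window (pre-deflection)
  mean(uv[seq_len(max(1L, floor(length(uv) / 4)))])
}

#' Spike amplitude
#'
#' Distance from baseline to the highest peak: the baseline is the mean of
#' the first quarter of the waveform window and the peak is the sample of
#' maximal absolute deviation from it (extracellular somatic spikes are
#' trough-dominant; the amplitude is reported unsigned).
#'
#' @param unit a \linkS4class{SpikeUnit}, or a data.frame/list with elements
#'   \code{time_ms} and \code{uv}.
#' @return amplitude in the waveform's voltage units.
#' @export
spikeAmplitude <- function(unit) {
  wf <- if (is(unit, "SpikeUnit")) waveform(unit) else unit
  dev <- wf$uv - waveformBaseline(wf$uv)
  amp <- max(abs(dev))
  if (amp == 0) stop("flat waveform: amplitude undefined")
  amp
}

#' Spike width at half amplitude
#'
#' Time between the two crossings of the half-amplitude level flanking the
#' extremum, with linear interpolation between samples.
#'
#' @inheritParams spikeAmplitude
#' @return width in ms.
#' @export
spikeWidth <- function(unit) {
  wf <- if (is(unit, "SpikeUnit")) waveform(unit) else unit
  dev <- wf$uv - waveformBaseline(wf$uv)
  ipk <- which.max(abs(dev))
  s <- sign(dev[ipk])
  y <- dev * s                               # peak now positive
  half <- y[ipk] / 2
  tms <- wf$time_ms
  crossAt <- function(i, j) {                # linear interpolation
    tms[i] + (half - y[i]) * (tms[j] - tms[i]) / (y[j] - y[i])
  }
  left <- NA_real_
  for (i in rev(seq_len(ipk - 1)))
    if (y[i] < half) { left <- crossAt(i, i + 1); break }
  right <- NA_real_
  if (ipk < length(y))
    for (i in (ipk + 1):length(y))
      if (y[i] < half) { right <- crossAt(i, i - 1); break }
  if (is.na(left) || is.na(right))
    stop("half-amplitude level not crossed on both sides of the peak")
  right - left
}

#' Compute all metrics for one unit
#'
#' @param unit a \linkS4class{SpikeUnit}.
#' @param duration recording duration, seconds.
#' @return a \linkS4class{UnitMetrics}.
#' @export
unitMetrics <- function(unit, duration) {
  acg <- spikeAutocorrelogram(unit)
  fm <- suppressWarnings(acgFirstMoment(acg))
  new("UnitMetrics", unitId = unitId(unit),
      firingRate = firingRate(unit, duration),
      spikeAmplitude = spikeAmplitude(unit), spikeWidth = spikeWidth(unit),
      acg = acg, acgFirstMoment = fm, layer = unitLayer(unit),
      animalId = unit@animalId, group = unitGroup(unit))
}

#' Metrics table for a list of units
#'
#' @param units list of \linkS4class{SpikeUnit}.
#' @param duration recording duration, seconds.
#' @return data.frame with one row per unit (unitId, firingRate,
#'   spikeAmplitude, spikeWidth, acgFirstMoment, layer, animalId, group).
#'   Units with fewer than 2 spikes are excluded with a warning rather than
#'   propagated as 0-Hz rows.
#' @export
unitMetricsTable <- function(units, duration) {
  keep <- vapply(units, function(u) length(spikeTimes(u)) >= 2, logical(1))
  if (any(!keep))
    warning(sum(!keep), " unit(s) with < 2 spikes excluded from metrics")
  rows <- lapply(units[keep], function(u) {
    m <- unitMetrics(u, duration)
    data.frame(unitId = m@unitId, firingRate = m@firingRate,
               spikeAmplitude = m@spikeAmplitude, spikeWidth = m@spikeWidth,
               acgFirstMoment = m@acgFirstMoment, layer = m@layer,
               animalId = m@animalId, group = m@group,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
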