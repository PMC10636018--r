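## Spike-LFP entrainment: instantaneous phase by zero-phase band-pass +
## analytic signal, mean vector length (MVL) per frequency band on the unit's
## max-amplitude channel, and per-band group comparison with merging of
## contiguous significant bins into reported frequency ranges.

#' Instantaneous phase of one LFP channel in a band
#'
#' Zero-phase FFT band-pass followed by the analytic-signal argument. Phase
#' convention: 0 at the oscillation peak, advancing through +pi/2 a quarter
#' cycle after the peak, in (-pi, pi].
#'
#' @param x numeric LFP trace (one channel).
#' @param fs sampling rate, Hz.
#' @param band numeric length-2 (low, high) in Hz, inside (0, fs/2).
#' @return numeric phase series, same length as \code{x}.
#' @export
bandPhase <- function(x, fs, band) {
  if (band[2] <= band[1]) stop("band must have positive width")
  if (band[2] > fs / 2) stop("band beyond Nyquist")
  Arg(fftBandpass(x, fs, band[1], band[2], analytic = TRUE))
}

#' Mean vector length
#'
#' Modulus of the mean unit vector of a phase sample:
#' \code{Mod(mean(exp(1i * phases)))}. 0 = no phase preference, 1 = perfect
#' locking. Under uniform phases the expected value is approximately
#' \code{sqrt(pi / (4 n))} (chance level).
#'
#' @param phases numeric phases, radians (n >= 1).
#' @return MVL in [0, 1]; NA with a warning for an empty phase set.
#' @export
mvl <- function(phases) {
  if (length(phases) == 0) {
    warning("empty phase set: MVL undefined")
    return(NA_real_)
  }
  Mod(mean(exp(1i * phases)))
}

#' Default entrainment band grid over 1-300 Hz
#'
#' Contiguous bins: 1 Hz wide below 12 Hz, 5 Hz wide from 12 to 302 Hz, so
#' that ranges such as 4-6 Hz and 62-82 Hz are unions of whole bins.
#'
#' @return data.frame with columns \code{low} and \code{high} (Hz).
#' @export
defaultBandGrid <- function() {
  lows <- c(1:11, seq(12, 297, by = 5))
  highs <- c(2:12, seq(17, 302, by = 5))
  data.frame(low = lows, high = highs)
}

## phase at arbitrary times by linear interpolation of the analytic signal
phaseAtTimes <- function(analytic, fs, times) {
  grid <- (seq_along(analytic) - 1) / fs
  re <- stats::approx(grid, Re(analytic), xout = times)$y
  im <- stats::approx(grid, Im(analytic), xout = times)$y
  atan2(im, re)
}

#' Spike-LFP entrainment profile of one unit
#'
#' For every band of the grid, band-passes the unit's max-amplitude channel,
#' evaluates the analytic-signal phase at the spike times and computes the
#' MVL. Spikes within one filter transient (1/bandwidth seconds, at least
#' 0.1 s) of the recording edges are dropped from each band's phase pool;
#' bands left with no spikes are flagged NA.
#'
#' @param unit a \linkS4class{SpikeUnit}.
#' @param lfp a \linkS4class{LaminarLFP} covering the unit's spikes.
#' @param bandGrid data.frame of band edges (default
#'   \code{\link{defaultBandGrid}}).
#' @return an \linkS4class{EntrainmentProfile}.
#' @export
entrainmentProfile <- function(unit, lfp, bandGrid = defaultBandGrid()) {
  ch <- maxChannel(unit)
  if (ch < 1 || ch > nChannels(lfp)) stop("unit max channel not in LFP")
  st <- spikeTimes(unit)
  dur <- recordingDuration(lfp)
  if (length(st) && max(st) > dur) stop("spikes outside the LFP duration")
  x <- lfpData(lfp)[ch, ]
  fs <- samplingRate(lfp)
  nb <- nrow(bandGrid)
  out <- rep(NA_real_, nb)
  ns <- integer(nb)
  for (b in seq_len(nb)) {
    lo <- bandGrid$low[b]; hi <- bandGrid$high[b]
    trim <- max(1 / (hi - lo), 0.1)
    pool <- st[st >= trim & st <= dur - trim]
    ns[b] <- length(pool)
    if (!length(pool)) next
    z <- fftBandpass(x, fs, lo, hi, analytic = TRUE)
    out[b] <- mvl(phaseAtTimes(z, fs, pool))
  }
  new("EntrainmentProfile", unitId = unitId(unit), bandLow = bandGrid$low,
      bandHigh = bandGrid$high, mvl = out, nSpikes = ns)
}

## merge contiguous significant bins into reported frequency ranges
mergeSignificantRuns <- function(bandLow, bandHigh, sig) {
  sig[is.na(sig)] <- FALSE
  if (!any(sig)) return(data.frame(low = numeric(0), high = numeric(0)))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(low = bandLow[starts[keep]], high = bandHigh[ends[keep]])
}

#' Group comparison of entrainment profiles
#'
#' Per band: group means with SEM and a two-sided Mann-Whitney p-value;
#' contiguous bands with p below alpha are merged into reported frequency
#' ranges. Bands in which either group has fewer than 2 defined units are
#' skipped with a warning.
#'
#' @param profiles list of \linkS4class{EntrainmentProfile} over a common
#'   band grid.
#' @param groups character vector of group labels, one per profile (two
#'   levels).
#' @param alpha significance threshold (default 0.05).
#' @return list with \code{perBand} (data.frame: band edges, means, SEMs, n,
#'   p) and \code{significantRanges} (data.frame of merged ranges with the
#'   direction of the difference).
#' @export
groupEntrainmentCompare <- function(profiles, groups, alpha = 0.05) {
  stopifnot(length(profiles) == length(groups))
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  bl <- profiles[[1]]@bandLow; bh <- profiles[[1]]@bandHigh
  m <- vapply(profiles, function(p) {
    if (!identical(p@bandLow, bl)) stop("profiles use different band grids")
    p@mvl
  }, numeric(length(bl)))
  skipped <- FALSE
  perBand <- do.call(rbind, lapply(seq_along(bl), function(b) {
    v1 <- m[b, groups == lev[1]]; v1 <- v1[!is.na(v1)]
    v2 <- m[b, groups == lev[2]]; v2 <- v2[!is.na(v2)]
    p <- NA_real_
    if (length(v1) >= 2 && length(v2) >= 2) {
      p <- suppressWarnings(stats::wilcox.test(v1, v2)$p.value)
    } else skipped <<- TRUE
    data.frame(low = bl[b], high = bh[b],
               mean1 = mean(v1), sem1 = sem(v1), n1 = length(v1),
               mean2 = mean(v2), sem2 = sem(v2), n2 = length(v2),
               p = p)
  }))
  names(perBand)[3:8] <- c(paste0("mean_", lev[1]), paste0("sem_", lev[1]),
                           paste0("n_", lev[1]), paste0("mean_", lev[2]),
                           paste0("sem_", lev[2]), paste0("n_", lev[2]))
  if (skipped) warning("bands with < 2 defined units per group were skipped")
  ranges <- mergeSignificantRuns(bl, bh, perBand$p < alpha)
  if (nrow(ranges)) {
    ranges$direction <- vapply(seq_len(nrow(ranges)), function(i) {
      idx <- which(bl >= ranges$low[i] & bh <= ranges$high[i])
      d <- mean(perBand[idx, 3] - perBand[idx, 6])
      if (d > 0) paste(lev[1], ">", lev[2]) else paste(lev[1], "<", lev[2])
    }, character(1))
  }
  list(perBand = perBand, significantRanges = ranges,
       groups = lev, alpha = alpha)
}
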