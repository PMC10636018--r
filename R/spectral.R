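## Spectral analysis: pyramidal-layer localization from high-frequency RMS
## power, Welch PSD per unit-bearing channel (with duplicate-channel
## exclusion), and z-scored group comparison with per-frequency t-tests and
## run-length merging of significant bins. The 58-62 Hz band around mains
## noise is excluded from testing and linearly interpolated in curves.

#' Locate the pyramidal layer from wideband high-frequency power
#'
#' Per-channel RMS of the 600-6000 Hz band-passed wideband signal, a proxy
#' for local spiking activity; the pyramidal layer is the channel of maximal
#' RMS. A flat profile (max/median below \code{flatRatio}) is flagged
#' non-informative.
#'
#' @param wideband a \linkS4class{LaminarLFP} sampled at >= 12 kHz.
#' @param flatRatio informativeness threshold on max/median RMS (default 1.5).
#' @return list with \code{channel} (argmax index), \code{profile}
#'   (per-channel RMS) and \code{informative} (logical).
#' @export
locatePyramidalLayer <- function(wideband, flatRatio = 1.5) {
  fs <- samplingRate(wideband)
  if (fs < 12000)
    stop("600-6000 Hz band needs a sampling rate of at least 12 kHz")
  dat <- lfpData(wideband)
  prof <- vapply(seq_len(nrow(dat)), function(ch) {
    bp <- fftBandpass(dat[ch, ], fs, 600, 6000)
    sqrt(mean(bp^2))
  }, numeric(1))
  list(channel = which.max(prof), profile = prof,
       informative = max(prof) / stats::median(prof) >= flatRatio)
}

#' Welch PSD of selected LFP channels
#'
#' @param lfp a \linkS4class{LaminarLFP}.
#' @param channels channel indices (default: all).
#' @param window,overlap Welch segment length (s) and fractional overlap.
#' @param maxFreq truncate the grid (default 300 Hz; use NULL for the full
#'   Nyquist band, e.g. for Parseval checks).
#' @return list with \code{freq} (Hz) and \code{power} (matrix, frequencies x
#'   channels, uV^2/Hz).
#' @export
computePsd <- function(lfp, channels = seq_len(nChannels(lfp)),
                       window = 2, overlap = 0.5, maxFreq = 300) {
  if (any(channels < 1 | channels > nChannels(lfp)))
    stop("invalid channel index")
  fs <- samplingRate(lfp)
  cols <- lapply(channels, function(ch)
    welchPsd(lfpData(lfp)[ch, ], fs, window, overlap, maxFreq))
  power <- do.call(cbind, lapply(cols, `[[`, "power"))
  colnames(power) <- paste0("ch", channels)
  list(freq = cols[[1]]$freq, power = power, channels = channels)
}

#' Unique unit-bearing channels
#'
#' If more than one single unit sits on the same channel, the duplicate power
#' spectrum is excluded: each channel is counted once.
#'
#' @param units list of \linkS4class{SpikeUnit}.
#' @return sorted integer vector of unique max-amplitude channels.
#' @export
dedupeUnitChannels <- function(units) {
  sort(unique(vapply(units, maxChannel, integer(1))))
}

## z-score a curve along the frequency axis
zscoreCurve <- function(x) (x - mean(x)) / stats::sd(x)

## linear interpolation across an excluded frequency band (mains notch)
interpolateNotch <- function(freq, curve, notch) {
  bad <- freq >= notch[1] & freq <= notch[2]
  if (!any(bad) || all(bad)) return(curve)
  curve[bad] <- stats::approx(freq[!bad], curve[!bad], xout = freq[bad],
                              rule = 2)$y
  curve
}

#' Z-scored group PSD comparison
#'
#' Each animal contributes one curve: the log10 power averaged over its
#' unit-bearing channels. Curves are z-scored along the frequency axis, the
#' mains band is interpolated out, groups are compared per frequency with a
#' two-sample t-test, and contiguous significant bins (p < alpha, mains band
#' excluded from testing) are merged into reported ranges.
#'
#' @param animalPsds list of per-animal PSDs as returned by
#'   \code{\link{computePsd}} (one entry per animal, channels already
#'   deduplicated).
#' @param groups character group label per animal (two levels).
#' @param alpha per-frequency significance threshold (default 0.01).
#' @param notch mains exclusion band, Hz (default c(58, 62)).
#' @return list with \code{freq}, \code{curves} (matrix animals x
#'   frequencies, z-scored), \code{groupMean}/\code{groupSd} (per group),
#'   \code{p} (per-frequency p-values, NA in the notch),
#'   \code{significantRanges} (merged runs with direction), \code{groups}.
#'   With a single-animal group, tests are skipped and curves still produced.
#' @export
zscoreGroupPsd <- function(animalPsds, groups, alpha = 0.01,
                           notch = c(58, 62)) {
  stopifnot(length(animalPsds) == length(groups))
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  freq <- animalPsds[[1]]$freq
  curves <- t(vapply(animalPsds, function(ps) {
    if (!identical(ps$freq, freq)) stop("animals use different PSD grids")
    curve <- rowMeans(log10(ps$power))
    zscoreCurve(interpolateNotch(freq, curve, notch))
  }, numeric(length(freq))))
  g1 <- curves[groups == lev[1], , drop = FALSE]
  g2 <- curves[groups == lev[2], , drop = FALSE]
  groupMean <- cbind(colMeans(g1), colMeans(g2))
  groupSd <- cbind(apply(g1, 2, stats::sd), apply(g2, 2, stats::sd))
  colnames(groupMean) <- colnames(groupSd) <- lev
  inNotch <- freq >= notch[1] & freq <= notch[2]
  p <- rep(NA_real_, length(freq))
  if (nrow(g1) >= 2 && nrow(g2) >= 2) {
    for (i in which(!inNotch))
      p[i] <- tryCatch(stats::t.test(g1[, i], g2[, i])$p.value,
                       error = function(e) NA_real_)
  } else warning("single-animal group: per-frequency tests skipped")
  ranges <- mergeSignificantRuns(freq, freq, p < alpha)
  if (nrow(ranges)) {
    ranges$direction <- vapply(seq_len(nrow(ranges)), function(i) {
      idx <- which(freq >= ranges$low[i] & freq <= ranges$high[i])
      d <- mean(groupMean[idx, 1] - groupMean[idx, 2])
      if (d > 0) paste(lev[1], ">", lev[2]) else paste(lev[1], "<", lev[2])
    }, character(1))
  }
  list(freq = freq, curves = curves, groupMean = groupMean,
       groupSd = groupSd, p = p, significantRanges = ranges,
       groups = lev, alpha = alpha, notch = notch)
}
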