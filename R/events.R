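## Hyperexcitability event detectors. The criteria follow the qualitative
## descriptions of the phenomena (a sustained negative deflection over 1 s
## across the laminar layers; synchronized 6-8 Hz paroxysmal rhythmic
## spikes); the detection constants (MAD multiplier, channel fraction,
## baseline windows) are calibration parameters exposed as arguments.

## find runs where `active` holds for >= minSamples; returns start/end indices
activeRuns <- function(active, minSamples, mergeGapSamples = 0) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  if (!length(on)) return(data.frame(start = integer(0), end = integer(0)))
  runs <- data.frame(start = starts[on], end = ends[on])
  if (mergeGapSamples > 0 && nrow(runs) > 1) {
    keep <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs$start[i] - last$end <= mergeGapSamples)
        keep[[length(keep)]]$end <- runs$end[i]
      else keep[[length(keep) + 1]] <- runs[i, ]
    }
    runs <- do.call(rbind, keep)
  }
  runs[runs$end - runs$start + 1 >= minSamples, , drop = FALSE]
}

## refine onset/offset of one event at 50 percent of its peak deflection
refineEdges <- function(trace, start, end, fs, positive = FALSE) {
  seg <- trace[start:end]
  peak <- if (positive) max(seg) else min(seg)
  lev <- peak / 2
  pad <- round(fs)                       # search up to 1 s around the run
  lo <- max(1, start - pad); hi <- min(length(trace), end + pad)
  cross <- if (positive) trace[lo:hi] >= lev else trace[lo:hi] <= lev
  ipk <- lo - 1 + (if (positive) which.max(trace[lo:hi])
                   else which.min(trace[lo:hi]))
  idx <- lo:hi
  left <- idx[cross & idx <= ipk]
  right <- idx[cross & idx >= ipk]
  c(onset = if (length(left)) min(left) else start,
    offset = if (length(right)) max(right) else end,
    peak = peak)
}

#' Detect sustained depolarizing shifts
#'
#' Per channel, the trace is low-passed below \code{lowpass} Hz and compared
#' to a rolling-median baseline; a channel is "deflected" where it falls
#' below baseline minus \code{k} times the channel's MAD. An event is emitted
#' where at least \code{channelFraction} of channels are deflected
#' simultaneously for at least \code{minDuration} seconds. Onset and offset
#' are refined at 50 percent of the event's peak deflection on the
#' channel-median trace.
#'
#' @param lfp a \linkS4class{LaminarLFP}, at least 10 s long.
#' @param k MAD multiplier (default 5).
#' @param minDuration minimum event duration, s (default 1.0).
#' @param channelFraction fraction of channels required (default 0.75).
#' @param lowpass low-pass corner, Hz (default 2).
#' @param baselineWindow rolling-median window, s (default 20).
#' @return data.frame event log: type, onset, duration, channelFraction,
#'   peak (uV).
#' @export
detectSustainedDepolarization <- function(lfp, k = 5, minDuration = 1.0,
                                          channelFraction = 0.75,
                                          lowpass = 2, baselineWindow = 20) {
  fs <- samplingRate(lfp)
  dur <- recordingDuration(lfp)
  if (dur < 10) stop("recording shorter than the 10 s baseline minimum")
  dat <- lfpData(lfp)
  n <- ncol(dat)
  nch <- nrow(dat)
  ## the trace is low-passed below `lowpass` Hz, so the rolling-median
  ## baseline is computed on a 20 Hz decimated copy and interpolated back
  ds <- max(1L, floor(fs / 20))
  idx <- seq(1L, n, by = ds)
  win <- min(round(baselineWindow * 20), length(idx) - 1)
  if (win %% 2 == 0) win <- win + 1
  deflected <- matrix(FALSE, nch, n)
  devMedian <- matrix(0, nch, n)
  grid <- (seq_len(n) - 1) / fs
  for (ch in seq_len(nch)) {
    lp <- fftBandpass(dat[ch, ], fs, 0, lowpass)
    baseDec <- stats::runmed(lp[idx], win, endrule = "median")
    base <- stats::approx(grid[idx], baseDec, xout = grid, rule = 2)$y
    dev <- lp - base
    deflected[ch, ] <- dev < -k * stats::mad(dev)
    devMedian[ch, ] <- dev
  }
  frac <- colMeans(deflected)
  runs <- activeRuns(frac >= channelFraction, round(minDuration * fs),
                     mergeGapSamples = round(0.2 * fs))
  if (!nrow(runs))
    return(data.frame(type = character(0), onset = numeric(0),
                      duration = numeric(0), channelFraction = numeric(0),
                      peak = numeric(0)))
  do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    ## cross-channel median trace, computed only around this run
    lo <- max(1L, runs$start[i] - round(2 * fs))
    hi <- min(n, runs$end[i] + round(2 * fs))
    med <- apply(devMedian[, lo:hi, drop = FALSE], 2, stats::median)
    e <- refineEdges(med, runs$start[i] - lo + 1L, runs$end[i] - lo + 1L, fs)
    data.frame(type = "depol_shift", onset = (lo + e["onset"] - 2) / fs,
               duration = (e["offset"] - e["onset"]) / fs,
               channelFraction = max(frac[runs$start[i]:runs$end[i]]),
               peak = e["peak"], row.names = NULL)
  }))
}

#' Detect paroxysmal rhythmic spikes (6-8 Hz synchronized activity)
#'
#' Per channel, the smoothed analytic-signal envelope of the 6-8 Hz band is
#' compared to a baseline threshold (channel median plus \code{k} MADs); an
#' event is emitted where at least \code{channelFraction} of channels exceed
#' their threshold simultaneously for at least \code{minCycles} cycles of the
#' band's center frequency. The criterion is co-elevated band power, not
#' cross-channel phase alignment. Onsets are refined at 50 percent of the
#' event's peak envelope on the channel-median envelope.
#'
#' @param lfp a \linkS4class{LaminarLFP}, at least 10 s long.
#' @param band frequency band, Hz (default c(6, 8)).
#' @param k MAD multiplier (default 5).
#' @param minCycles minimum duration in cycles of the band center (default 3).
#' @param channelFraction fraction of channels required (default 0.75).
#' @return data.frame event log: type, onset, duration, channelFraction,
#'   peak (median cross-channel envelope ratio to baseline at the peak).
#' @export
detectParoxysmalSpikes <- function(lfp, band = c(6, 8), k = 5,
                                   minCycles = 3, channelFraction = 0.75) {
  fs <- samplingRate(lfp)
  if (recordingDuration(lfp) < 10)
    stop("recording shorter than the 10 s baseline minimum")
  dat <- lfpData(lfp)
  nch <- nrow(dat)
  smoothN <- max(1L, round(0.25 * fs))
  ## centered moving average via cumulative sums (O(n))
  movavg <- function(x, w) {
    half <- w %/% 2
    cs <- cumsum(c(0, x))
    n <- length(x)
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  env <- matrix(0, nch, ncol(dat))
  thr <- numeric(nch)
  baseMed <- numeric(nch)
  for (ch in seq_len(nch)) {
    e <- Mod(fftBandpass(dat[ch, ], fs, band[1], band[2], analytic = TRUE))
    e <- movavg(e, smoothN)
    env[ch, ] <- e
    baseMed[ch] <- stats::median(e)
    thr[ch] <- baseMed[ch] + k * stats::mad(e)
  }
  above <- env > thr
  frac <- colMeans(above)
  minDur <- minCycles / mean(band)
  runs <- activeRuns(frac >= channelFraction, round(minDur * fs),
                     mergeGapSamples = round(0.2 * fs))
  if (!nrow(runs))
    return(data.frame(type = character(0), onset = numeric(0),
                      duration = numeric(0), channelFraction = numeric(0),
                      peak = numeric(0)))
  n <- ncol(dat)
  do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    ## cross-channel median envelope, computed only around this run
    lo <- max(1L, runs$start[i] - round(2 * fs))
    hi <- min(n, runs$end[i] + round(2 * fs))
    medEnv <- apply(env[, lo:hi, drop = FALSE], 2, stats::median)
    e <- refineEdges(medEnv, runs$start[i] - lo + 1L, runs$end[i] - lo + 1L,
                     fs, positive = TRUE)
    ratio <- stats::median(
      apply(env[, runs$start[i]:runs$end[i], drop = FALSE], 1, max) / baseMed)
    data.frame(type = "rhythmic_spikes", onset = (lo + e["onset"] - 2) / fs,
               duration = (e["offset"] - e["onset"]) / fs,
               channelFraction = max(frac[runs$start[i]:runs$end[i]]),
               peak = ratio, row.names = NULL)
  }))
}
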