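## Synthetic laminar recordings: 1/f background + narrowband oscillators with
## Gaussian depth profiles, plus phase-locked spike trains generated by exact
## point-process thinning so the expected mean vector length of a tonic unit
## is the analytic Bessel ratio I1(kappa)/I0(kappa).

#' SynthConfig: the stated world of the synthetic generator
#'
#' Defaults encode the recording conditions and printed group statistics of
#' the porcine concussion study this pipeline targets: 32-channel laminar
#' probe, LFP at 2 kHz, class mean firing rates (pyramidal 2.27 / 1.70 Hz,
#' interneuron 7.46 / 3.09 Hz for control / post-mTBI), waveform templates at
#' the printed amplitude and width means, and von Mises locking
#' concentrations chosen so the population resultant lengths equal the
#' printed entrainment values (e.g. 0.020 at 62-82 Hz for control pyramidal
#' cells, 0.041 at 4-6 Hz for post-mTBI interneurons).
#'
#' @slot duration recording length, seconds.
#' @slot samplingRate LFP sampling rate, Hz (>= 2000).
#' @slot nChannels,channelSpacing probe geometry (count, micrometres).
#' @slot group "control" or "post_mtbi".
#' @slot nPyramidal,nInterneuron,nDentate unit counts; dentate test units are
#'   placed below the pyramidal layer.
#' @slot rateParams per-class firing-rate distribution (lognormal mean,
#'   sdlog, truncation bounds).
#' @slot burstParams per-class burst structure (mean geometric burst length,
#'   intra-burst ISI ms, ISI jitter ms); meanBurstLength 1 = tonic.
#' @slot lockingSpecs per-class von Mises locking (band edges Hz,
#'   concentration kappa, preferred phase rad).
#' @slot oscillatorSpecs narrowband oscillators (freq Hz, amplitude uV,
#'   Gaussian depth-profile center channel and width in channels).
#' @slot noiseExponent,noiseAmplitude 1/f^exponent background and its RMS uV.
#' @slot waveformTemplates per-class template amplitude (uV) and width (ms).
#' @slot waveformJitter fractional per-unit jitter of amplitude and width.
#' @slot eventSpecs optional event injections (see \code{\link{injectEvents}}).
#' @slot seed master RNG seed; one stream per unit is derived by stable
#'   hashing so adding units does not perturb existing ones.
#' @export
setClass("SynthConfig",
  representation(duration = "numeric", samplingRate = "numeric",
                 nChannels = "integer", channelSpacing = "numeric",
                 group = "character", nPyramidal = "integer",
                 nInterneuron = "integer", nDentate = "integer",
                 rateParams = "data.frame", burstParams = "data.frame",
                 lockingSpecs = "data.frame", oscillatorSpecs = "data.frame",
                 noiseExponent = "numeric", noiseAmplitude = "numeric",
                 waveformTemplates = "data.frame", waveformJitter = "numeric",
                 eventSpecs = "dataFrameOrNULL", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- NULL
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@samplingRate < 2000)
    msg <- c(msg, "samplingRate must be >= 2 kHz")
  if (any(object@rateParams$mean <= 0)) msg <- c(msg, "rates must be > 0")
  if (any(object@lockingSpecs$kappa < 0)) msg <- c(msg, "kappa must be >= 0")
  if (object@noiseAmplitude < 0) msg <- c(msg, "noise amplitude must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Build a synthetic-recording configuration
#'
#' @param duration seconds (default 600, the horizon at which configured
#'   rates are recovered within 5 percent).
#' @param samplingRate Hz, >= 2000.
#' @param nChannels,channelSpacing probe geometry.
#' @param group "control" or "post_mtbi"; switches the class statistics,
#'   oscillator amplitudes and locking strengths to the respective group's
#'   printed values.
#' @param nPyramidal,nInterneuron,nDentate unit counts per class.
#' @param rateParams,burstParams,lockingSpecs,oscillatorSpecs,waveformTemplates
#'   override the group defaults (see \linkS4class{SynthConfig}).
#' @param noiseExponent,noiseAmplitude 1/f background exponent and RMS (uV).
#' @param waveformJitter fractional per-unit jitter on template parameters.
#' @param eventSpecs data.frame of events to inject, or NULL.
#' @param seed master seed (integer).
#' @return a validated \linkS4class{SynthConfig}.
#' @export
synthConfig <- function(duration = 600, samplingRate = 2000,
                        nChannels = 32L, channelSpacing = 100,
                        group = c("control", "post_mtbi"),
                        nPyramidal = 7L, nInterneuron = 6L, nDentate = 0L,
                        rateParams = NULL, burstParams = NULL,
                        lockingSpecs = NULL, oscillatorSpecs = NULL,
                        noiseExponent = 1, noiseAmplitude = 100,
                        waveformTemplates = NULL, waveformJitter = 0.05,
                        eventSpecs = NULL, seed = 1L) {
  group <- match.arg(group)
  ctrl <- group == "control"
  if (is.null(rateParams))
    rateParams <- data.frame(
      class = c("pyramidal", "interneuron"),
      mean  = if (ctrl) c(2.27, 7.46) else c(1.70, 3.09),
      sdlog = c(0.4, 0.25),
      min   = c(0.2, if (ctrl) 7.3 else 0.5),
      max   = c(6.7, 25))
  if (is.null(burstParams))
    burstParams <- data.frame(
      class = c("pyramidal", "interneuron"),
      meanBurstLength = c(3, 1),
      intraBurstIsiMs = c(5, NA),
      isiJitterMs = c(0.5, NA))
  if (is.null(lockingSpecs))
    lockingSpecs <- data.frame(
      class = c("pyramidal", "pyramidal", "interneuron"),
      low   = c(62, 103, 4),
      high  = c(82, 117, 6),
      kappa = if (ctrl) c(0.040, 0.036, 0.026) else c(0.010, 0.006, 0.082),
      prefPhase = c(0, 0, 0))
  if (is.null(oscillatorSpecs)) {
    gammaScale <- if (ctrl) 1 else 0.6   # -40 percent gamma and HFO post-mTBI
    oscillatorSpecs <- data.frame(
      freq = c(5, 55, 72, 110, 150),
      amplitude = c(150, 40 * gammaScale, 30 * gammaScale,
                    15 * gammaScale, 10 * gammaScale),
      centerChannel = c(22, 10, 10, 10, 10),
      widthChannels = c(8, 6, 6, 5, 5))
  }
  if (is.null(waveformTemplates))
    waveformTemplates <- data.frame(
      class = c("pyramidal", "interneuron"),
      amplitude = if (ctrl) c(256, 367) else c(238, 170),
      width     = if (ctrl) c(0.336, 0.373) else c(0.280, 0.263))
  new("SynthConfig", duration = duration, samplingRate = samplingRate,
      nChannels = as.integer(nChannels), channelSpacing = channelSpacing,
      group = group, nPyramidal = as.integer(nPyramidal),
      nInterneuron = as.integer(nInterneuron), nDentate = as.integer(nDentate),
      rateParams = rateParams, burstParams = burstParams,
      lockingSpecs = lockingSpecs, oscillatorSpecs = oscillatorSpecs,
      noiseExponent = noiseExponent, noiseAmplitude = noiseAmplitude,
      waveformTemplates = waveformTemplates, waveformJitter = waveformJitter,
      eventSpecs = eventSpecs, seed = as.integer(seed))
}

## default laminar annotation: top half of the probe is the CA1 pyramidal
## layer, bottom half below it (radiatum/moleculare/dentate side)
defaultLayers <- function(nChannels) {
  c(rep("ca1_pyr", ceiling(nChannels / 2)),
    rep("below_pyr", floor(nChannels / 2)))
}

onefNoise <- function(n, fs, exponent, rmsAmplitude) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- ifelse(f > fs / 2, fs - f, f)
  shape <- c(0, f[-1]^(-exponent / 2))
  y <- Re(stats::fft(X * shape, inverse = TRUE) / n)
  y * rmsAmplitude / stats::sd(y)
}

#' Generate a synthetic laminar LFP
#'
#' 1/f-spectrum background noise plus narrowband sinusoidal oscillators, each
#' scaled across channels by a Gaussian depth profile. The generating
#' oscillator table (with the drawn initial phases) is stored in the returned
#' object and serves as analytic ground-truth phase for every band.
#' Deterministic given the config seed.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return a \linkS4class{LaminarLFP}.
#' @export
generateLFP <- function(config) {
  validObject(config)
  n <- round(config@duration * config@samplingRate)
  nch <- config@nChannels
  t <- (seq_len(n) - 1) / config@samplingRate
  osc <- config@oscillatorSpecs
  if (nrow(osc)) {
    osc$phi0 <- vapply(seq_len(nrow(osc)), function(o)
      withSeed(subSeed(config@seed, 1000L + o), stats::runif(1, -pi, pi)),
      numeric(1))
  } else osc$phi0 <- numeric(0)
  data <- matrix(0, nrow = nch, ncol = n)
  if (config@noiseAmplitude > 0)
    for (ch in seq_len(nch))
      data[ch, ] <- withSeed(subSeed(config@seed, ch),
        onefNoise(n, config@samplingRate, config@noiseExponent,
                  config@noiseAmplitude))
  for (o in seq_len(nrow(osc))) {
    wave <- osc$amplitude[o] * cos(2 * pi * osc$freq[o] * t + osc$phi0[o])
    depth <- exp(-((seq_len(nch) - osc$centerChannel[o])^2) /
                   (2 * osc$widthChannels[o]^2))
    data <- data + outer(depth, wave)
  }
  lfp <- new("LaminarLFP", data = data, samplingRate = config@samplingRate,
             spacing = config@channelSpacing, layers = defaultLayers(nch),
             oscillators = osc, events = NULL, group = config@group,
             animalId = "synthetic")
  if (!is.null(config@eventSpecs) && nrow(config@eventSpecs))
    lfp <- injectEvents(lfp, config@eventSpecs)
  lfp
}

#' Analytic ground-truth phase of a generating oscillator
#'
#' @param lfp a synthetic \linkS4class{LaminarLFP} carrying its oscillator
#'   table.
#' @param band numeric length-2, Hz; the (unique) oscillator inside the band
#'   is used.
#' @param times seconds at which to evaluate the phase.
#' @return phases in (-pi, pi], 0 at the oscillation peak.
#' @export
oscillatorPhase <- function(lfp, band, times) {
  osc <- oscillators(lfp)
  if (is.null(osc) || !nrow(osc)) stop("LFP carries no oscillator ground truth")
  hit <- which(osc$freq >= band[1] & osc$freq <= band[2])
  if (!length(hit))
    stop("no oscillator inside band ", band[1], "-", band[2], " Hz")
  hit <- hit[1]
  wrapPhase(2 * pi * osc$freq[hit] * times + osc$phi0[hit])
}

## intensity of the phase-modulated point process, normalized by I0(kappa)
## per band so the mean rate stays at the configured value
phaseIntensity <- function(times, rate, locks, lfp) {
  lam <- rep(rate, length(times))
  for (b in seq_len(nrow(locks))) {
    phi <- oscillatorPhase(lfp, c(locks$low[b], locks$high[b]), times)
    lam <- lam * exp(locks$kappa[b] * cos(phi - locks$prefPhase[b])) /
      besselI(locks$kappa[b], 0)
  }
  lam
}

## exact thinning of an inhomogeneous Poisson process on [0, duration]
thinnedTimes <- function(rate, locks, lfp, duration) {
  lamMax <- rate * prod(exp(locks$kappa) / besselI(locks$kappa, 0))
  nCand <- stats::rpois(1, lamMax * duration)
  if (nCand == 0) return(numeric(0))
  cand <- sort(stats::runif(nCand, 0, duration))
  keep <- stats::runif(nCand) < phaseIntensity(cand, rate, locks, lfp) / lamMax
  cand[keep]
}

spikeTemplate <- function(amplitude, width, fsWave = 32000) {
  tms <- seq(0, 2, by = 1000 / fsWave)       # 2 ms window at 32 kHz
  sigma <- width / (2 * sqrt(2 * log(2)))    # FWHM = configured width
  uv <- -amplitude * exp(-(tms - 1)^2 / (2 * sigma^2)) +
    0.15 * amplitude * exp(-(tms - 1.6)^2 / (2 * 0.15^2))
  data.frame(time_ms = tms, uv = uv)
}

#' Generate phase-locked synthetic spike trains
#'
#' Interneurons are tonic inhomogeneous Poisson processes with intensity
#' \code{r * exp(kappa * cos(phi(t) - phi0)) / I0(kappa)}, drawn by exact
#' thinning against the analytic oscillator phase, so the expected mean
#' vector length equals \code{I1(kappa)/I0(kappa)} and the mean rate stays
#' \code{r}. Pyramidal units are burst-renewal processes (phase-modulated
#' burst onsets, geometric burst lengths, jittered intra-burst ISIs) with the
#' same locking mechanism. Each unit carries its class waveform template with
#' small multiplicative jitter and a max-amplitude channel inside the
#' annotated pyramidal layer (below it for dentate test units).
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param lfp the \linkS4class{LaminarLFP} produced by
#'   \code{\link{generateLFP}} from the same config.
#' @return list of \linkS4class{SpikeUnit}.
#' @export
generateSpikeTrains <- function(config, lfp) {
  validObject(config)
  osc <- oscillators(lfp)
  if (is.null(osc)) stop("lfp must carry oscillator ground truth")
  for (b in seq_len(nrow(config@lockingSpecs))) {
    ls <- config@lockingSpecs[b, ]
    if (!any(osc$freq >= ls$low & osc$freq <= ls$high))
      stop("locking band ", ls$low, "-", ls$high,
           " Hz has no oscillator in oscillatorSpecs")
  }
  lay <- layers(lfp)
  plan <- data.frame(
    class = c(rep("pyramidal", config@nPyramidal),
              rep("interneuron", config@nInterneuron),
              rep("interneuron", config@nDentate)),
    layer = c(rep("ca1_pyr", config@nPyramidal + config@nInterneuron),
              rep("below_pyr", config@nDentate)))
  units <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    cls <- plan$class[i]
    rp <- config@rateParams[config@rateParams$class == cls, ]
    bp <- config@burstParams[config@burstParams$class == cls, ]
    wt <- config@waveformTemplates[config@waveformTemplates$class == cls, ]
    locks <- config@lockingSpecs[config@lockingSpecs$class == cls, ]
    units[[i]] <- withSeed(subSeed(config@seed, 2000L + i), {
      repeat {
        rate <- stats::rlnorm(1, log(rp$mean) - rp$sdlog^2 / 2, rp$sdlog)
        if (rate >= rp$min && rate <= rp$max) break
      }
      bursty <- bp$meanBurstLength > 1
      if (bursty) {
        onsets <- thinnedTimes(rate / bp$meanBurstLength, locks, lfp,
                               config@duration)
        st <- unlist(lapply(onsets, function(t0) {
          len <- 1L + stats::rgeom(1, 1 / bp$meanBurstLength)
          isis <- pmax(1, bp$intraBurstIsiMs +
                         stats::rnorm(len - 1, 0, bp$isiJitterMs)) / 1000
          t0 + c(0, cumsum(isis))
        }))
      } else {
        st <- thinnedTimes(rate, locks, lfp, config@duration)
      }
      st <- as.numeric(st)
      st <- sort(st[st >= 0 & st <= config@duration])
      ## enforce strictly increasing times (coincident burst collisions);
      ## no refractory pruning: it would bias the MVL calibration by
      ## preferentially deleting spikes at the preferred phase
      if (length(st) > 1) st <- st[c(TRUE, diff(st) > 1e-9)]
      ampJ <- 1 + stats::runif(1, -config@waveformJitter, config@waveformJitter)
      widJ <- 1 + stats::runif(1, -config@waveformJitter, config@waveformJitter)
      tpl <- spikeTemplate(wt$amplitude * ampJ, wt$width * widJ)
      chPool <- which(lay == plan$layer[i])
      ch <- chPool[1L + (i %% length(chPool))]
      new("SpikeUnit", unitId = sprintf("u%02d_%s", i, substr(cls, 1, 3)),
          spikeTimes = st, waveformTime = tpl$time_ms, waveformUv = tpl$uv,
          maxChannel = as.integer(ch), layer = plan$layer[i],
          animalId = "synthetic", group = config@group,
          groundTruth = list(class = cls, rate = rate,
                             amplitude = wt$amplitude * ampJ,
                             width = wt$width * widJ, locks = locks))
    })
  }
  units
}

raisedCosineStep <- function(t, t0, t1, ramp) {
  ## 0 before t0, 1 on the plateau, smooth raised-cosine ramps of given width
  up <- pmin(pmax((t - t0) / ramp, 0), 1)
  down <- pmin(pmax((t1 - t) / ramp, 0), 1)
  (0.5 - 0.5 * cos(pi * up)) * (0.5 - 0.5 * cos(pi * down))
}

#' Inject ground-truth hyperexcitability events into an LFP
#'
#' Adds (a) a sustained negative DC shift ("depol_shift": stated amplitude
#' and duration, smooth 50 ms raised-cosine onset/offset) and/or (b) a
#' rhythmic spike-wave train ("rhythmic_spikes": sharp negative transients at
#' the stated frequency) across the stated fraction of channels (counted from
#' the top of the probe), synchronized across channels. The ground-truth log
#' is appended to the object's event slot.
#'
#' @param lfp a \linkS4class{LaminarLFP}.
#' @param eventSpecs data.frame with columns \code{type} ("depol_shift" or
#'   "rhythmic_spikes"), \code{onset} and \code{duration} (s),
#'   \code{amplitude} (uV; negative for a depolarizing shift),
#'   \code{freq} (Hz, rhythmic events only; NA otherwise) and
#'   \code{channelFraction} in (0, 1].
#' @return the modified \linkS4class{LaminarLFP} with ground-truth log.
#' @export
injectEvents <- function(lfp, eventSpecs) {
  if (is.null(eventSpecs) || !nrow(eventSpecs)) return(lfp)
  fs <- samplingRate(lfp)
  dur <- recordingDuration(lfp)
  n <- ncol(lfp@data)
  t <- (seq_len(n) - 1) / fs
  for (e in seq_len(nrow(eventSpecs))) {
    ev <- eventSpecs[e, ]
    if (ev$onset < 0 || ev$onset + ev$duration > dur)
      stop("event ", e, " lies outside the recording duration")
    nch <- max(1L, ceiling(ev$channelFraction * nChannels(lfp)))
    chans <- seq_len(nch)
    if (ev$type == "depol_shift") {
      shape <- ev$amplitude *
        raisedCosineStep(t, ev$onset, ev$onset + ev$duration, 0.05)
    } else if (ev$type == "rhythmic_spikes") {
      pulses <- seq(ev$onset, ev$onset + ev$duration, by = 1 / ev$freq)
      shape <- numeric(n)
      halfw <- 0.012                        # 12 ms sharp transient
      for (tk in pulses) {
        idx <- which(t >= tk - 5 * halfw & t <= tk + 5 * halfw)
        shape[idx] <- shape[idx] +
          ev$amplitude * exp(-(t[idx] - tk)^2 / (2 * halfw^2))
      }
    } else stop("unknown event type: ", ev$type)
    lfp@data[chans, ] <- lfp@data[chans, , drop = FALSE] +
      matrix(shape, nrow = length(chans), ncol = n, byrow = TRUE)
  }
  log <- eventSpecs
  lfp@events <- if (is.null(lfp@events)) log else rbind(lfp@events, log)
  lfp
}
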