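# Small in-code fixtures shared across the test files. Everything is
# generated programmatically under fixed seeds; no data files.

# compact synthetic recording: few channels, short duration
tinyConfig <- function(duration = 20, nChannels = 4L, seed = 11L, ...) {
  synthConfig(duration = duration, nChannels = nChannels, seed = seed, ...)
}

# a triangular test waveform with known geometry: baseline `base`,
# negative peak of size `amp` at `peakMs`, linear flanks
triangleWaveform <- function(amp = 300, base = 0, peakMs = 1,
                             riseMs = 0.4, fallMs = 0.6, dtMs = 1 / 32) {
  t <- seq(0, 2, by = dtMs)
  up <- pmax(0, 1 - abs(t - peakMs) / riseMs) * (t <= peakMs)
  dn <- pmax(0, 1 - abs(t - peakMs) / fallMs) * (t > peakMs)
  data.frame(time_ms = t, uv = base - amp * (up + dn))
}

# metrics table for a two-class population cleanly separated across 7 Hz:
# slow/bursty/wide "pyramidal" vs fast/tonic/narrow "interneuron" units
separatedMetrics <- function(nPerClass = 50, seed = 7L) {
  set.seed(seed)
  data.frame(
    unitId = sprintf("u%03d", seq_len(2 * nPerClass)),
    firingRate = c(pmax(0.3, pmin(6.5, rnorm(nPerClass, 2, 1))),
                   pmax(7.5, rnorm(nPerClass, 12, 2))),
    spikeAmplitude = c(rnorm(nPerClass, 300, 30),
                       rnorm(nPerClass, 350, 30)),
    spikeWidth = c(rnorm(nPerClass, 0.35, 0.02),
                   rnorm(nPerClass, 0.25, 0.02)),
    acgFirstMoment = c(rnorm(nPerClass, 12, 2), rnorm(nPerClass, 26, 2)),
    layer = "ca1_pyr",
    animalId = "a1",
    group = "control",
    trueClass = rep(c("pyramidal", "interneuron"), each = nPerClass),
    stringsAsFactors = FALSE)
}

# entrainment profile whose per-band MVLs come from von Mises phase pools
profileFromKappa <- function(id, bands, kappa, nSpikes = 6000) {
  vals <- vapply(seq_len(nrow(bands)), function(b)
    mvl(rvonmises(nSpikes, 0, kappa[b])), numeric(1))
  new("EntrainmentProfile", unitId = id, bandLow = bands$low,
      bandHigh = bands$high, mvl = vals,
      nSpikes = rep(as.integer(nSpikes), nrow(bands)))
}

# fast model params for tests: shorter stimulus, coarser-but-converged step
testPvParams <- function(...) {
  pvModelParams(stimDuration = 400, ...)
}
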