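# Synthetic generator: determinism, spectral content of the background and
# oscillators, point-process rate and phase-locking calibration, event
# injection round trips.

test_that("generation is bit-identical under a fixed seed", {
  cfg <- tinyConfig(duration = 10)
  lfp1 <- generateLFP(cfg)
  lfp2 <- generateLFP(cfg)
  expect_identical(lfpData(lfp1), lfpData(lfp2))
  u1 <- generateSpikeTrains(cfg, lfp1)
  u2 <- generateSpikeTrains(cfg, lfp2)
  expect_identical(lapply(u1, spikeTimes), lapply(u2, spikeTimes))
  expect_identical(waveform(u1[[1]]), waveform(u2[[1]]))
  # different seed changes the output
  lfp3 <- generateLFP(tinyConfig(duration = 10, seed = 12L))
  expect_false(identical(lfpData(lfp1), lfpData(lfp3)))
})

test_that("adding units does not perturb existing unit streams", {
  cfg1 <- tinyConfig(duration = 10, nPyramidal = 2L, nInterneuron = 1L)
  cfg2 <- tinyConfig(duration = 10, nPyramidal = 2L, nInterneuron = 3L)
  lfp <- generateLFP(cfg1)
  u1 <- generateSpikeTrains(cfg1, lfp)
  u2 <- generateSpikeTrains(cfg2, lfp)
  for (i in seq_along(u1))
    expect_identical(spikeTimes(u1[[i]]), spikeTimes(u2[[i]]))
})

test_that("a single oscillator with no noise dominates the PSD at its frequency", {
  cfg <- tinyConfig(duration = 20, noiseAmplitude = 0,
                    oscillatorSpecs = data.frame(freq = 5, amplitude = 100,
                                                 centerChannel = 2,
                                                 widthChannels = 50))
  lfp <- generateLFP(cfg)
  for (ch in c(1, 4)) {
    ps <- welchPsd(lfpData(lfp)[ch, ], samplingRate(lfp), window = 4)
    expect_equal(ps$freq[which.max(ps$power)], 5, tolerance = 0.3)
  }
})

test_that("pure 1/f background has log-log PSD slope near -1 over 1-300 Hz", {
  cfg <- tinyConfig(duration = 60, nChannels = 2L,
                    oscillatorSpecs = data.frame(freq = numeric(0),
                                                 amplitude = numeric(0),
                                                 centerChannel = numeric(0),
                                                 widthChannels = numeric(0)),
                    noiseExponent = 1)
  lfp <- generateLFP(cfg)
  ps <- welchPsd(lfpData(lfp)[1, ], samplingRate(lfp), window = 2,
                 maxFreq = 300)
  keep <- ps$freq >= 1
  fit <- lm(log10(power) ~ log10(freq), data = ps[keep, ])
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.15)
})

test_that("configured tonic rate is recovered within 5 percent at 600 s", {
  cfg <- tinyConfig(duration = 600, nChannels = 2L, nPyramidal = 0L,
                    nInterneuron = 1L,
                    rateParams = data.frame(class = "interneuron", mean = 10,
                                            sdlog = 1e-6, min = 9.9,
                                            max = 10.1))
  lfp <- generateLFP(cfg)
  u <- generateSpikeTrains(cfg, lfp)[[1]]
  expect_equal(firingRate(u, 600), 10, tolerance = 0.05)
})

test_that("kappa = 0 produces no measurable phase preference", {
  cfg <- tinyConfig(duration = 120, nChannels = 2L, nPyramidal = 0L,
                    nInterneuron = 1L,
                    rateParams = data.frame(class = "interneuron", mean = 50,
                                            sdlog = 1e-6, min = 49, max = 51),
                    lockingSpecs = data.frame(class = "interneuron", low = 4,
                                              high = 6, kappa = 0,
                                              prefPhase = 0))
  lfp <- generateLFP(cfg)
  u <- generateSpikeTrains(cfg, lfp)[[1]]
  phases <- oscillatorPhase(lfp, c(4, 6), spikeTimes(u))
  n <- length(phases)
  # chance level for uniform phases is ~ sqrt(pi/(4 n))
  expect_lt(mvl(phases), 3 * sqrt(pi / (4 * n)))
})

test_that("empirical MVL of a locked train matches the Bessel-ratio ground truth", {
  # ~4e5 spikes: the analytic resultant I1(k)/I0(k) should be hit to 0.003
  cfg <- tinyConfig(duration = 1200, nChannels = 1L, nPyramidal = 0L,
                    nInterneuron = 1L, noiseAmplitude = 0,
                    rateParams = data.frame(class = "interneuron", mean = 350,
                                            sdlog = 1e-6, min = 340,
                                            max = 360),
                    lockingSpecs = data.frame(class = "interneuron", low = 4,
                                              high = 6, kappa = 1,
                                              prefPhase = 0.5))
  lfp <- generateLFP(cfg)
  u <- generateSpikeTrains(cfg, lfp)[[1]]
  expect_gt(length(spikeTimes(u)), 1e5)
  phases <- oscillatorPhase(lfp, c(4, 6), spikeTimes(u))
  expect_equal(mvl(phases), vonMisesResultant(1), tolerance = 0.003 /
                 vonMisesResultant(1))
  # preferred phase is recovered too
  expect_equal(Arg(mean(exp(1i * phases))), 0.5, tolerance = 0.02)
})

test_that("phase modulation does not change the mean rate", {
  base <- list(class = "interneuron", mean = 40, sdlog = 1e-6,
               min = 39, max = 41)
  mk <- function(kappa) {
    cfg <- tinyConfig(duration = 300, nChannels = 1L, nPyramidal = 0L,
                      nInterneuron = 8L,
                      rateParams = as.data.frame(base),
                      lockingSpecs = data.frame(class = "interneuron",
                                                low = 4, high = 6,
                                                kappa = kappa,
                                                prefPhase = 0))
    lfp <- generateLFP(cfg)
    mean(vapply(generateSpikeTrains(cfg, lfp),
                firingRate, numeric(1), duration = 300))
  }
  r0 <- mk(0)
  r2 <- mk(2)
  # both within sampling error (3 SE pooled over 8 units) of 40 Hz
  tol <- 3 * sqrt(40 / (300 * 8)) / 40
  expect_equal(r0, 40, tolerance = tol)
  expect_equal(r2, 40, tolerance = tol)
  # and the modulated process is not slower/faster than the unmodulated one
  expect_equal(r2 / r0, 1, tolerance = 2 * tol)
})

test_that("bursty pyramidal units have smaller ACG first moment than tonic units", {
  cfg <- tinyConfig(duration = 120, nChannels = 2L, nPyramidal = 1L,
                    nInterneuron = 1L,
                    rateParams = data.frame(class = c("pyramidal",
                                                      "interneuron"),
                                            mean = c(5, 5), sdlog = 1e-6,
                                            min = 4.9, max = 5.1))
  lfp <- generateLFP(cfg)
  us <- generateSpikeTrains(cfg, lfp)
  fm <- vapply(us, function(u)
    acgFirstMoment(spikeAutocorrelogram(u)), numeric(1))
  cls <- vapply(us, function(u) groundTruth(u)$class, character(1))
  expect_lt(fm[cls == "pyramidal"], fm[cls == "interneuron"])
})

test_that("waveform templates carry the configured amplitude and width", {
  cfg <- tinyConfig(duration = 10, waveformJitter = 0)
  lfp <- generateLFP(cfg)
  us <- generateSpikeTrains(cfg, lfp)
  for (u in us) {
    gt <- groundTruth(u)
    expect_equal(spikeAmplitude(u), gt$amplitude, tolerance = 0.01)
    expect_equal(spikeWidth(u), gt$width, tolerance = 1 / 32 / gt$width)
  }
})

test_that("unit max channels respect the laminar annotation", {
  cfg <- tinyConfig(duration = 10, nPyramidal = 2L, nInterneuron = 2L,
                    nDentate = 2L)
  lfp <- generateLFP(cfg)
  us <- generateSpikeTrains(cfg, lfp)
  lay <- layers(lfp)
  for (u in us) expect_identical(lay[maxChannel(u)], unitLayer(u))
  expect_identical(sum(vapply(us, unitLayer, "") == "below_pyr"), 2L)
})

test_that("event injection modifies the signal and logs ground truth; empty specs are identity", {
  cfg <- tinyConfig(duration = 30)
  lfp <- generateLFP(cfg)
  expect_identical(lfpData(injectEvents(lfp, NULL)), lfpData(lfp))
  spec <- data.frame(type = "depol_shift", onset = 10, duration = 1.2,
                     amplitude = -800, freq = NA, channelFraction = 1)
  out <- injectEvents(lfp, spec)
  expect_equal(nrow(eventLog(out)), 1)
  # plateau is shifted by the stated amplitude, outside untouched
  i <- round(10.6 * samplingRate(lfp))
  expect_equal(lfpData(out)[1, i] - lfpData(lfp)[1, i], -800)
  j <- round(5 * samplingRate(lfp))
  expect_equal(lfpData(out)[1, j], lfpData(lfp)[1, j])
})

test_that("invalid configurations and events are rejected", {
  expect_error(synthConfig(duration = -1), "duration")
  expect_error(synthConfig(samplingRate = 500), "2 kHz")
  expect_error(
    synthConfig(lockingSpecs = data.frame(class = "interneuron", low = 4,
                                          high = 6, kappa = -1,
                                          prefPhase = 0)),
    "kappa")
  cfg <- tinyConfig(duration = 10)
  lfp <- generateLFP(cfg)
  expect_error(injectEvents(lfp, data.frame(type = "depol_shift", onset = 9.5,
                                            duration = 2, amplitude = -100,
                                            freq = NA, channelFraction = 1)),
               "outside")
  # locking band without an oscillator
  bad <- tinyConfig(duration = 10,
                    lockingSpecs = data.frame(class = "interneuron", low = 200,
                                              high = 210, kappa = 1,
                                              prefPhase = 0))
  expect_error(generateSpikeTrains(bad, lfp), "no oscillator")
})
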