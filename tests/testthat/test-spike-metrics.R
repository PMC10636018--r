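# Unit metrics: rate, autocorrelogram (against an O(n^2) brute-force
# oracle), first moment, waveform amplitude/width geometry, and the wavelet
# high-pass filter.

# independent O(n^2) oracle: count all ordered pairs per 1 ms lag
bruteAcg <- function(st) {
  d <- outer(st, st, "-")
  d <- d[d > 0] * 1000
  counts <- vapply(1:50, function(l) sum(d > l - 0.5 & d <= l + 0.5),
                   numeric(1))
  if (sum(counts) > 0) counts / sum(counts) else counts
}

test_that("firing rate is spikes per second", {
  expect_equal(firingRate(seq(0.05, by = 0.1, length.out = 100), 10), 10)
  train <- seq(0, by = 0.02, length.out = 3000)   # 20 ms ISI over 60 s
  expect_equal(firingRate(train[train < 60], 60), 50)
  expect_error(firingRate(c(1, 2), 0), "duration")
  expect_warning(r <- firingRate(numeric(0), 10), "zero spikes")
  expect_equal(r, 0)
})

test_that("ACG matches brute-force pair counting exactly", {
  set.seed(3)
  trains <- list(
    regular = seq(0, by = 0.02, length.out = 1000),
    poisson = sort(runif(800, 0, 40)),
    bursty = sort(as.vector(outer(c(0, 0.005, 0.011),
                                  cumsum(rexp(300, 3)), FUN = "+")))
  )
  for (nm in names(trains)) {
    st <- trains[[nm]]
    expect_equal(spikeAutocorrelogram(st), bruteAcg(st), label = nm)
  }
})

test_that("regular 20 ms train puts equal mass at 20 and 40 ms lags", {
  st <- seq(0, by = 0.02, length.out = 1000)
  acg <- spikeAutocorrelogram(st)
  expect_equal(acg[20] + acg[40], 1)
  expect_equal(acg[20], 0.5, tolerance = 0.01)
  # first moment ~ 0.5*20 + 0.5*40 = 30 ms, within one 1 ms bin
  expect_equal(acgFirstMoment(acg), 30, tolerance = 1 / 30)
})

test_that("two spikes 10 ms apart give a point mass at lag 10", {
  acg <- spikeAutocorrelogram(c(0.1, 0.11))
  expect_equal(acg[10], 1)
  expect_equal(sum(acg), 1)
  expect_equal(acgFirstMoment(acg), 10)
})

test_that("homogeneous Poisson ACG is flat", {
  set.seed(8)
  st <- sort(runif(25000, 0, 50))   # 500 Hz: many pairs per lag
  acg <- spikeAutocorrelogram(st)
  # pairs in (0.5, 50.5] ms, counted without materializing the pair matrix
  nPairs <- sum(findInterval(st + 0.0505, st) -
                  findInterval(st + 0.0005, st))
  counts <- acg * nPairs
  # chi-square flatness check against the uniform distribution over 50 lags
  chisq <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chisq, qchisq(0.999, df = 49))
})

test_that("degenerate ACG inputs are handled", {
  expect_error(spikeAutocorrelogram(0.5), "at least 2")
  acg <- spikeAutocorrelogram(c(0, 10))   # no pair within 50 ms
  expect_equal(sum(acg), 0)
  expect_warning(fm <- acgFirstMoment(acg), "undefined")
  expect_true(is.na(fm))
  # flat acg has first moment 25.5
  expect_equal(acgFirstMoment(rep(1 / 50, 50)), 25.5)
})

test_that("amplitude is baseline-to-extremum and width is measured at half level", {
  wf <- triangleWaveform(amp = 300, base = 0)
  expect_equal(spikeAmplitude(wf), 300, tolerance = 1e-6)
  # half crossings of a triangle: half-way up each flank
  expect_equal(spikeWidth(wf), (0.4 + 0.6) / 2, tolerance = 1e-6)
  # baseline offset is subtracted
  wf2 <- triangleWaveform(amp = 300, base = 50)
  expect_equal(spikeAmplitude(wf2), 300, tolerance = 1e-6)
  # amplitude scales linearly, width is scale-invariant
  wf3 <- wf
  wf3$uv <- wf3$uv * 2
  expect_equal(spikeAmplitude(wf3), 600, tolerance = 1e-6)
  expect_equal(spikeWidth(wf3), spikeWidth(wf), tolerance = 1e-9)
})

test_that("width and amplitude are invariant to time shift and resampling", {
  # peaks on the sample grid, rising flank clear of the baseline window
  wf <- triangleWaveform(amp = 250, peakMs = 1.0)
  shifted <- triangleWaveform(amp = 250, peakMs = 1.25)
  expect_equal(spikeAmplitude(shifted), spikeAmplitude(wf), tolerance = 1e-6)
  expect_equal(spikeWidth(shifted), spikeWidth(wf), tolerance = 1e-6)
  coarse <- triangleWaveform(amp = 250, dtMs = 4 / 32)  # 4x coarser
  expect_equal(spikeWidth(coarse), spikeWidth(wf), tolerance = (4 / 32) / 0.5)
})

test_that("malformed waveforms raise errors", {
  flat <- data.frame(time_ms = seq(0, 2, by = 1 / 16), uv = 0)
  expect_error(spikeAmplitude(flat), "flat")
  # peak at the very edge: no right-side crossing
  t <- seq(0, 2, by = 1 / 16)
  ramp <- data.frame(time_ms = t, uv = c(rep(0, 16), seq(0, -300,
                                                length.out = length(t) - 16)))
  expect_error(spikeWidth(ramp), "not crossed")
})

test_that("unitMetrics bundles the per-unit metrics consistently", {
  cfg <- tinyConfig(duration = 60)
  lfp <- generateLFP(cfg)
  us <- generateSpikeTrains(cfg, lfp)
  m <- unitMetrics(us[[1]], 60)
  expect_s4_class(m, "UnitMetrics")
  expect_equal(m@firingRate, firingRate(us[[1]], 60))
  expect_equal(sum(m@acg), 1)
  tab <- unitMetricsTable(us, 60)
  expect_equal(nrow(tab), length(us))
  expect_true(all(tab$acgFirstMoment >= 1 & tab$acgFirstMoment <= 50))
})

test_that("wavelet high-pass removes DC and low frequencies, keeps fast bursts", {
  n <- 2048
  # DC offset is removed
  out <- waveletHighpass(rep(5, n))
  expect_lt(max(abs(out)), 1e-9)
  # zeros in, zeros out
  expect_equal(waveletHighpass(numeric(n)), numeric(n))
  # a high-frequency burst far above the cutoff passes nearly unchanged
  t <- seq_len(n)
  burst <- exp(-((t - 1024) / 40)^2) * sin(2 * pi * t / 6)
  out <- waveletHighpass(burst)
  expect_gt(cor(out, burst), 0.99)
  # a smooth low-frequency wave is removed even with a burst riding on it
  drift <- 100 * sin(2 * pi * t / 1024)
  filtered <- waveletHighpass(burst * 50 + drift)
  expect_gt(cor(filtered, burst), 0.95)
  expect_lt(mean(abs(filtered - burst * 50)) / 50, 0.2)
  expect_error(waveletHighpass(rnorm(32), level = 6), "2\\^level")
})

test_that("wavelet transform reconstructs perfectly when nothing is zeroed", {
  # internal round trip: analysis + synthesis is the identity
  set.seed(4)
  x <- rnorm(512)
  s <- laminar:::dwtStepPeriodic(x, laminar:::db4Lowpass)
  xr <- laminar:::idwtStepPeriodic(s$a, s$d, laminar:::db4Lowpass)
  expect_equal(xr, x, tolerance = 1e-9)
})
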