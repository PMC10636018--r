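# Fast-spiking interneuron model: steady-state curves, window-current
# overlap (against a closed-form logistic oracle), simulation contracts,
# factor triples, the perturbation scan and best fit.

# closed-form overlap of two logistic curves (rising m, falling h) crossing
# at Vx: area = km log(1 + e^((Vx-mMid)/km)) + kh log(1 + e^(-(Vx-hMid)/kh))
logisticOverlapOracle <- function(mMid, km, hMid, kh, lo = -100, hi = 20) {
  f <- function(v) pmin(1 / (1 + exp(-(v - mMid) / km)),
                        1 / (1 + exp((v - hMid) / kh)))
  integrate(f, lo, hi, rel.tol = 1e-10)$value
}

test_that("steady-state curves are Boltzmann with the advertised midpoints", {
  p <- pvModelParams()
  ss <- steadyStates(p)
  expect_true(all(ss$mInf >= 0 & ss$mInf <= 1))
  expect_true(all(diff(ss$mInf) > 0))      # rising
  expect_true(all(diff(ss$hInf) < 0))      # falling
  # h_inf is 0.5 at its plotted midpoint (-35 mV at baseline)
  expect_equal(hInfMidpoint(p), -35)
  expect_equal(approx(ss$v, ss$hInf, xout = -35)$y, 0.5, tolerance = 1e-6)
  # the best-fit shift moves the midpoint from -35 to -44.5 mV
  pFit <- pvModelParams(thInf = -59)
  expect_equal(hInfMidpoint(pFit), -44.5)
  ssFit <- steadyStates(pFit)
  expect_equal(approx(ssFit$v, ssFit$hInf, xout = -44.5)$y, 0.5,
               tolerance = 1e-6)
  # activation is not altered by the h-only perturbation
  expect_equal(ssFit$mInf, ss$mInf)
})

test_that("window area matches the closed-form logistic oracle", {
  p <- pvModelParams()
  v <- seq(-100, 20, by = 0.002)
  ss <- steadyStates(p, v)
  oracle <- logisticOverlapOracle(p$mHalf, p$mSlope, hInfMidpoint(p),
                                  p$hSlope)
  expect_equal(windowCurrentArea(ss$mInf, ss$hInf, v), oracle,
               tolerance = 1e-6 / oracle)
  # mirror-symmetric curves crossing at 0.5
  sym <- steadyStates(pvModelParams(mHalf = -40, mSlope = 7, thInf = -54.5),
                      v)
  expect_equal(windowCurrentArea(sym$mInf, sym$hInf, v),
               logisticOverlapOracle(-40, 7, -40, 7),
               tolerance = 1e-6)
  expect_error(windowCurrentArea(ss$mInf[-1], ss$hInf, v), "mismatch")
})

test_that("window area strictly decreases under hyperpolarizing h shifts", {
  base <- pvModelParams()
  areas <- vapply(c(-49.5, -52, -55, -59, -62), function(th) {
    ss <- steadyStates(pvModelParams(thInf = th))
    windowCurrentArea(ss$mInf, ss$hInf, ss$v)
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
  # the -35 -> -44.5 mV best-fit shift: regression-locked relative decrease
  wc <- windowCurrentChange(base, pvModelParams(thInf = -59))
  expect_gt(wc$relativeChange, 0)
  expect_equal(wc$relativeChange, 0.4328, tolerance = 1e-3)
  # invariant under equal shifts of both curves (range extended so the
  # overlap is not clipped)
  v <- seq(-200, 120, by = 0.01)
  a0 <- steadyStates(base, v)
  a1 <- steadyStates(pvModelParams(sh = 10), v)
  expect_equal(windowCurrentArea(a1$mInf, a1$hInf, v),
               windowCurrentArea(a0$mInf, a0$hInf, v), tolerance = 1e-6)
})

test_that("zero stimulus settles to rest; identical params give identical traces", {
  p <- testPvParams(stimAmp = 0)
  tr <- simulatePV(p)
  expect_length(tr@spikeTimes, 0)
  nV <- length(tr@voltage)
  expect_lt(abs(tr@voltage[nV] - tr@voltage[nV - 1]) / p$dt, 1e-6)
  tr2 <- simulatePV(p)
  expect_identical(tr@voltage, tr2@voltage)
})

test_that("baseline fires repetitively and features converge under step halving", {
  tr <- simulatePV(testPvParams())
  expect_gt(tr@firingRate, 5)
  expect_gt(tr@spikeAmplitude, 50)     # tens-of-mV action potentials
  expect_lt(tr@spikeWidth, 1)          # sub-ms fast-spiking waveform
  trHalf <- simulatePV(testPvParams(dt = 0.005))
  expect_equal(tr@firingRate, trHalf@firingRate, tolerance = 0.01)
  expect_equal(tr@spikeWidth, trHalf@spikeWidth, tolerance = 0.01)
  expect_equal(tr@spikeAmplitude, trHalf@spikeAmplitude, tolerance = 0.01)
})

test_that("factor triple of baseline against itself is (1, 1, 1)", {
  tr <- simulatePV(testPvParams())
  expect_equal(unname(factorTriple(tr, tr)), c(1, 1, 1))
})

test_that("hyperpolarizing thInf shifts monotonically reduce all three factors", {
  base <- simulatePV(testPvParams())
  fts <- vapply(c(-55, -57, -59, -60), function(th)
    factorTriple(simulatePV(testPvParams(thInf = th)), base), numeric(3))
  expect_true(all(fts < 1))
  expect_true(all(diff(fts["rateFactor", ]) < 0))
  expect_true(all(diff(fts["widthFactor", ]) < 0))
  expect_true(all(diff(fts["amplitudeFactor", ]) < 0))
})

test_that("integration failure is reported with diagnostics", {
  expect_error(simulatePV(testPvParams(stimAmp = 1e5)),
               "integration failure")
})

test_that("parameter scan reports factors, flags failures, and best fit works", {
  cond <- tableOneConditions()
  res <- parameterScan(cond, baseline = testPvParams())
  expect_equal(nrow(res$scan), nrow(cond))
  # every spiking condition has finite factors; failed rows are NA
  ok <- res$scan$spiked
  expect_true(all(is.finite(as.matrix(
    res$scan[ok, c("rateFactor", "widthFactor", "amplitudeFactor")]))))
  expect_true(all(is.na(res$scan$rateFactor[!ok])))
  # dendritic rows are flagged non-comparable
  expect_false(any(res$scan$comparable[grep("dend", res$scan$label)]))
  bf <- bestFit(res, cond, baseline = testPvParams())
  expect_equal(nrow(bf), 1)
  # best fit is a pure h-inactivation shift and beats the unperturbed model
  expect_match(bf$label, "^thInf=")
  expect_equal(bf$nPerturbed, 1)
  lossBaseline <- sum((c(1, 1, 1) - c(0.41, 0.71, 0.46))^2)
  expect_lt(bf$loss, lossBaseline)
  # forced degenerate grid: baseline only
  condBase <- data.frame(label = "baseline", thInf = NA, eNa = NA, sh = NA,
                         gKdr = NA, comparable = TRUE)
  resBase <- parameterScan(condBase, baseline = testPvParams())
  bfBase <- bestFit(resBase, condBase, baseline = testPvParams())
  expect_equal(bfBase$loss, lossBaseline, tolerance = 1e-10)
  expect_error(parameterScan(cond[0, ]), "empty")
})

test_that("experimental factor triple from the printed group means", {
  # post-injury vs control interneuron ratios: rate 3.09/7.46, width
  # 0.263/0.373, amplitude 170/367
  exp3 <- c(3.09 / 7.46, 0.263 / 0.373, 170 / 367)
  expect_equal(round(exp3, 2), c(0.41, 0.71, 0.46))
  expect_equal(round(100 * (1 - exp3)), c(59, 29, 54))
})
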