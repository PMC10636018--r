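## Single-compartment Hodgkin-Huxley-type model of a fast-spiking PV+ basket
## cell: leak + transient sodium (m^3 h) + delayed-rectifier potassium (n^4),
## Boltzmann steady states with bell-shaped voltage-dependent time constants,
## integrated with fixed-step RK4. The sodium inactivation midpoint is
## parameterized two ways, mirroring the two conventions in circulation for
## this cell model: an internal parameter `thInf` (the scan/fit handle) and
## the plotted midpoint `thInf + hMidpointOffset + sh`, so the baseline
## thInf = -49.5 corresponds to a plotted h_inf midpoint of -35 mV and the
## best-fit thInf = -59 to -44.5 mV.

#' Parameters of the fast-spiking interneuron model
#'
#' All conductances in mS/cm^2, voltages in mV, time constants in ms,
#' stimulus in uA/cm^2. Perturbations are expressed by setting \code{thInf},
#' \code{eNa}, \code{sh} or \code{gKdr} away from the frozen baseline.
#'
#' @param cm membrane capacitance, uF/cm^2.
#' @param gL,eL leak conductance and reversal.
#' @param gNa,eNa sodium maximal conductance and reversal.
#' @param mHalf,mSlope sodium activation midpoint and slope.
#' @param thInf sodium inactivation midpoint parameter; the plotted h_inf
#'   midpoint is \code{thInf + hMidpointOffset + sh}.
#' @param hSlope sodium inactivation slope (positive; the curve falls).
#' @param hMidpointOffset fixed offset between the internal parameter and
#'   the plotted midpoint.
#' @param sh voltage shift applied to both sodium gate midpoints.
#' @param gKdr,eK delayed-rectifier conductance and potassium reversal.
#' @param nHalf,nSlope potassium activation midpoint and slope.
#' @param tauMBase,tauMAmp,tauHBase,tauHAmp,tauNBase,tauNAmp gate
#'   time-constant parameters: tau(V) = base + amp / cosh((V - mid)/(2 k)).
#' @param stimAmp,stimDelay,stimDuration current-step stimulus (uA/cm^2, ms,
#'   ms). The default amplitude is the smallest value of a 0.1 uA/cm^2 grid
#'   giving repetitive firing of at least 5 Hz at baseline (frozen).
#' @param dt integration step, ms.
#' @return object of class \code{PVModelParams} (a validated list).
#' @export
pvModelParams <- function(cm = 1, gL = 0.1, eL = -65,
                          gNa = 100, eNa = 55,
                          mHalf = -35, mSlope = 6,
                          thInf = -49.5, hSlope = 7, hMidpointOffset = 14.5,
                          sh = 0,
                          gKdr = 25, eK = -90, nHalf = -30, nSlope = 6,
                          tauMBase = 0.01, tauMAmp = 0.02,
                          tauHBase = 0.2, tauHAmp = 0.6,
                          tauNBase = 0.1, tauNAmp = 0.3,
                          stimAmp = 0.7, stimDelay = 50,
                          stimDuration = 500, dt = 0.01) {
  p <- list(cm = cm, gL = gL, eL = eL, gNa = gNa, eNa = eNa,
            mHalf = mHalf, mSlope = mSlope, thInf = thInf, hSlope = hSlope,
            hMidpointOffset = hMidpointOffset, sh = sh, gKdr = gKdr,
            eK = eK, nHalf = nHalf, nSlope = nSlope,
            tauMBase = tauMBase, tauMAmp = tauMAmp, tauHBase = tauHBase,
            tauHAmp = tauHAmp, tauNBase = tauNBase, tauNAmp = tauNAmp,
            stimAmp = stimAmp, stimDelay = stimDelay,
            stimDuration = stimDuration, dt = dt)
  if (any(c(gL, gNa, gKdr) < 0)) stop("conductances must be >= 0")
  if (mSlope == 0 || hSlope == 0 || nSlope == 0)
    stop("gate slopes must be nonzero")
  if (eNa <= eL) stop("sodium reversal must exceed the resting range")
  class(p) <- "PVModelParams"
  p
}

#' Plotted h_inf midpoint of a parameter set
#'
#' @param params a \code{\link{pvModelParams}} object.
#' @return midpoint voltage, mV.
#' @export
hInfMidpoint <- function(params)
  params$thInf + params$hMidpointOffset + params$sh

#' Steady-state activation and inactivation curves
#'
#' Boltzmann curves: rising activation m_inf, falling inactivation h_inf,
#' both in [0, 1]; \code{thInf} and \code{sh} shift the respective midpoints.
#'
#' @param params a \code{\link{pvModelParams}} object.
#' @param v voltage grid, mV (default -100..20 in 0.05 mV steps).
#' @return data.frame with columns \code{v}, \code{mInf}, \code{hInf}.
#' @export
steadyStates <- function(params, v = seq(-100, 20, by = 0.05)) {
  mMid <- params$mHalf + params$sh
  hMid <- hInfMidpoint(params)
  data.frame(v = v,
             mInf = 1 / (1 + exp(-(v - mMid) / params$mSlope)),
             hInf = 1 / (1 + exp((v - hMid) / params$hSlope)))
}

#' Sodium window-current overlap area
#'
#' The window current is the overlap of the activation and inactivation
#' curves, quantified as \code{integral of min(m_inf, h_inf) dV} by the
#' trapezoid rule over the common grid.
#'
#' @param mInf,hInf curves on a common voltage grid.
#' @param v the voltage grid, mV.
#' @return area in mV (dimensionless conductance fraction times mV).
#' @export
windowCurrentArea <- function(mInf, hInf, v) {
  if (length(mInf) != length(v) || length(hInf) != length(v))
    stop("curves and voltage grid have mismatched lengths")
  y <- pmin(mInf, hInf)
  sum(diff(v) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Relative change of the window-current area under a perturbation
#'
#' @param baseline,perturbed \code{\link{pvModelParams}} objects.
#' @param v voltage grid (default -100..20 mV).
#' @return list with \code{baselineArea}, \code{perturbedArea} and
#'   \code{relativeChange} = 1 - perturbed/baseline (positive for a
#'   decrease).
#' @export
windowCurrentChange <- function(baseline, perturbed,
                                v = seq(-100, 20, by = 0.05)) {
  b <- steadyStates(baseline, v)
  p <- steadyStates(perturbed, v)
  ab <- windowCurrentArea(b$mInf, b$hInf, v)
  ap <- windowCurrentArea(p$mInf, p$hInf, v)
  list(baselineArea = ab, perturbedArea = ap, relativeChange = 1 - ap / ab)
}

#' Simulated membrane-voltage trajectory
#'
#' @slot time time grid, ms.
#' @slot voltage membrane voltage, mV.
#' @slot spikeTimes detected spike times, ms (upward 0 mV crossings with a
#'   1 ms lockout).
#' @slot firingRate steady-state rate, Hz.
#' @slot spikeWidth width at half amplitude of the mean spike waveform, ms.
#' @slot spikeAmplitude baseline-to-peak amplitude of the mean waveform, mV.
#' @slot meanWaveform mean aligned spike waveform (time_ms, uv columns; mV
#'   despite the column name shared with extracellular waveforms).
#' @export
setClass("SimTrace",
  representation(time = "numeric", voltage = "numeric",
                 spikeTimes = "numeric", firingRate = "numeric",
                 spikeWidth = "numeric", spikeAmplitude = "numeric",
                 meanWaveform = "data.frame"))

setMethod("show", "SimTrace", function(object) {
  cat(sprintf(
    "SimTrace: %.0f ms, %d spikes; rate %.2f Hz, width %.3f ms, amplitude %.1f mV\n",
    max(object@time), length(object@spikeTimes), object@firingRate,
    object@spikeWidth, object@spikeAmplitude))
})

#' Simulate the fast-spiking interneuron model
#'
#' Integrates the four-variable system (V, m, h, n) with fixed-step RK4
#' under a constant suprathreshold current step. Spikes are upward crossings
#' of 0 mV with a 1 ms lockout; the firing rate is taken over the stimulus
#' window after a 100 ms settling period, and spike width/amplitude are
#' computed on the mean aligned waveform with the same operators used for
#' experimental waveforms (shared definitions).
#'
#' @param params a \code{\link{pvModelParams}} object.
#' @return a \linkS4class{SimTrace}.
#' @export
simulatePV <- function(params) {
  p <- params
  dt <- p$dt
  tEnd <- p$stimDelay + p$stimDuration + 50
  n <- floor(tEnd / dt) + 1L
  time <- (seq_len(n) - 1) * dt
  mMid <- p$mHalf + p$sh
  hMid <- hInfMidpoint(p)
  ## constants hoisted out of the integration loop
  mS <- p$mSlope; hS <- p$hSlope; nS <- p$nSlope; nMid <- p$nHalf
  gNa <- p$gNa; eNa <- p$eNa; gK <- p$gKdr; eK <- p$eK
  gL <- p$gL; eL <- p$eL; cm <- p$cm
  tmB <- p$tauMBase; tmA <- p$tauMAmp; thB <- p$tauHBase; thA <- p$tauHAmp
  tnB <- p$tauNBase; tnA <- p$tauNAmp
  V <- p$eL
  ss0 <- steadyStates(p, V)
  m <- ss0$mInf; h <- ss0$hInf
  nn <- 1 / (1 + exp(-(V - nMid) / nS))
  voltage <- numeric(n)
  voltage[1] <- V
  spikes <- numeric(0)
  lastSpike <- -Inf
  stimOn <- p$stimDelay; stimOff <- p$stimDelay + p$stimDuration
  ## RK4 written out with scalar arithmetic (an allocating derivative
  ## closure is ~10x slower in R)
  for (i in 2:n) {
    tPrev <- time[i - 1]
    I <- if (tPrev >= stimOn && tPrev < stimOff) p$stimAmp else 0
    dv1 <- (I - gNa * m^3 * h * (V - eNa) - gK * nn^4 * (V - eK) -
              gL * (V - eL)) / cm
    dm1 <- (1 / (1 + exp(-(V - mMid) / mS)) - m) /
      (tmB + tmA / cosh((V - mMid) / (2 * mS)))
    dh1 <- (1 / (1 + exp((V - hMid) / hS)) - h) /
      (thB + thA / cosh((V - hMid) / (2 * hS)))
    dn1 <- (1 / (1 + exp(-(V - nMid) / nS)) - nn) /
      (tnB + tnA / cosh((V - nMid) / (2 * nS)))
    v2 <- V + dt / 2 * dv1; m2 <- m + dt / 2 * dm1
    h2 <- h + dt / 2 * dh1; n2 <- nn + dt / 2 * dn1
    dv2 <- (I - gNa * m2^3 * h2 * (v2 - eNa) - gK * n2^4 * (v2 - eK) -
              gL * (v2 - eL)) / cm
    dm2 <- (1 / (1 + exp(-(v2 - mMid) / mS)) - m2) /
      (tmB + tmA / cosh((v2 - mMid) / (2 * mS)))
    dh2 <- (1 / (1 + exp((v2 - hMid) / hS)) - h2) /
      (thB + thA / cosh((v2 - hMid) / (2 * hS)))
    dn2 <- (1 / (1 + exp(-(v2 - nMid) / nS)) - n2) /
      (tnB + tnA / cosh((v2 - nMid) / (2 * nS)))
    v3 <- V + dt / 2 * dv2; m3 <- m + dt / 2 * dm2
    h3 <- h + dt / 2 * dh2; n3 <- nn + dt / 2 * dn2
    dv3 <- (I - gNa * m3^3 * h3 * (v3 - eNa) - gK * n3^4 * (v3 - eK) -
              gL * (v3 - eL)) / cm
    dm3 <- (1 / (1 + exp(-(v3 - mMid) / mS)) - m3) /
      (tmB + tmA / cosh((v3 - mMid) / (2 * mS)))
    dh3 <- (1 / (1 + exp((v3 - hMid) / hS)) - h3) /
      (thB + thA / cosh((v3 - hMid) / (2 * hS)))
    dn3 <- (1 / (1 + exp(-(v3 - nMid) / nS)) - n3) /
      (tnB + tnA / cosh((v3 - nMid) / (2 * nS)))
    v4 <- V + dt * dv3; m4 <- m + dt * dm3
    h4 <- h + dt * dh3; n4 <- nn + dt * dn3
    dv4 <- (I - gNa * m4^3 * h4 * (v4 - eNa) - gK * n4^4 * (v4 - eK) -
              gL * (v4 - eL)) / cm
    dm4 <- (1 / (1 + exp(-(v4 - mMid) / mS)) - m4) /
      (tmB + tmA / cosh((v4 - mMid) / (2 * mS)))
    dh4 <- (1 / (1 + exp((v4 - hMid) / hS)) - h4) /
      (thB + thA / cosh((v4 - hMid) / (2 * hS)))
    dn4 <- (1 / (1 + exp(-(v4 - nMid) / nS)) - n4) /
      (tnB + tnA / cosh((v4 - nMid) / (2 * nS)))
    Vn <- V + dt / 6 * (dv1 + 2 * dv2 + 2 * dv3 + dv4)
    m <- m + dt / 6 * (dm1 + 2 * dm2 + 2 * dm3 + dm4)
    h <- h + dt / 6 * (dh1 + 2 * dh2 + 2 * dh3 + dh4)
    nn <- nn + dt / 6 * (dn1 + 2 * dn2 + 2 * dn3 + dn4)
    if (abs(Vn) > 200)
      stop("integration failure: |V| > 200 mV at t = ", round(time[i], 2),
           " ms (dt = ", dt, ")")
    if (V < 0 && Vn >= 0 && time[i] - lastSpike > 1) {
      spikes <- c(spikes, time[i])
      lastSpike <- time[i]
    }
    V <- Vn
    voltage[i] <- V
  }
  ## steady-state analysis window: stimulus on, after 100 ms settling
  w0 <- p$stimDelay + 100
  w1 <- p$stimDelay + p$stimDuration
  inWin <- spikes >= w0 & spikes <= w1
  ## steady-state rate from the mean inter-spike interval (finer resolution
  ## than a count over the window); falls back to the count for < 2 spikes
  rate <- if (sum(inWin) >= 2) {
    sw <- spikes[inWin]
    (length(sw) - 1) / ((sw[length(sw)] - sw[1]) / 1000)
  } else sum(inWin) / ((w1 - w0) / 1000)
  width <- NA_real_; amp <- NA_real_
  mw <- data.frame(time_ms = numeric(0), uv = numeric(0))
  if (sum(inWin) >= 2) {
    half <- round(1.5 / dt)
    segs <- lapply(spikes[inWin], function(ts) {
      ic <- round(ts / dt) + 1L
      ipk <- ic - 1 + which.max(voltage[ic:min(n, ic + round(1 / dt))])
      if (ipk - half < 1 || ipk + half > n) return(NULL)
      voltage[(ipk - half):(ipk + half)]
    })
    segs <- segs[!vapply(segs, is.null, logical(1))]
    if (length(segs)) {
      avg <- Reduce(`+`, segs) / length(segs)
      mw <- data.frame(time_ms = (seq_along(avg) - 1) * dt, uv = avg)
      amp <- spikeAmplitude(mw)
      width <- spikeWidth(mw)
    }
  }
  new("SimTrace", time = time, voltage = voltage, spikeTimes = spikes,
      firingRate = rate, spikeWidth = width, spikeAmplitude = amp,
      meanWaveform = mw)
}

#' Factor triple of a perturbed trace relative to baseline
#'
#' Elementwise ratios perturbed/baseline of (firing rate, spike width, spike
#' amplitude); a baseline compared with itself gives (1, 1, 1).
#'
#' @param perturbed,baseline \linkS4class{SimTrace} objects that both spiked.
#' @return named numeric: rateFactor, widthFactor, amplitudeFactor.
#' @export
factorTriple <- function(perturbed, baseline) {
  b <- c(baseline@firingRate, baseline@spikeWidth, baseline@spikeAmplitude)
  p <- c(perturbed@firingRate, perturbed@spikeWidth, perturbed@spikeAmplitude)
  if (any(is.na(b)) || any(b == 0))
    stop("baseline trace has undefined or zero features")
  stats::setNames(p / b, c("rateFactor", "widthFactor", "amplitudeFactor"))
}

#' Perturbation conditions of the published parameter scan
#'
#' The scan rows of the basket-cell table: single and combined perturbations
#' of the sodium inactivation midpoint (thInf), sodium reversal (eNa), gate
#' shift (sh) and fast delayed-rectifier conductance (gKdr, printed in S/cm^2
#' and converted to mS/cm^2 here). Rows that perturbed individual dendritic
#' sections in the multi-compartment original are mapped to whole-cell
#' perturbations and flagged \code{comparable = FALSE}, since a
#' single-compartment model cannot express them.
#'
#' @return data.frame with one row per condition: label, thInf, eNa, sh,
#'   gKdr (NA = baseline value) and comparable.
#' @export
tableOneConditions <- function() {
  data.frame(
    label = c("thInf=-59", "thInf=-60", "thInf=-59.5 eNa=80",
              "thInf=-57 eNa=80 sh=15.5 gKdr=26",
              "thInf=-57 sh=15.5 gKdr=26", "thInf=-58 eNa=70 gKdr=26",
              "thInf=-59.3 eNa=80", "dend(1,2) thInf=-59.3",
              "dend(0-3) thInf=-59.3 eNa=65", "dend(0,1) eNa=65",
              "dend(2,3) thInf=-59.3 eNa=70",
              "dend(0,5,10,13) thInf=-59.3 eNa=60",
              "dend(0,5,10,13) thInf=-59.5 eNa=65"),
    thInf = c(-59, -60, -59.5, -57, -57, -58, -59.3, -59.3, -59.3, NA,
              -59.3, -59.3, -59.5),
    eNa = c(NA, NA, 80, 80, NA, 70, 80, NA, 65, 65, 70, 60, 65),
    sh = c(NA, NA, NA, 15.5, 15.5, NA, NA, NA, NA, NA, NA, NA, NA),
    gKdr = c(NA, NA, NA, 26, 26, 26, NA, NA, NA, NA, NA, NA, NA),
    comparable = c(rep(TRUE, 7), rep(FALSE, 6)),
    stringsAsFactors = FALSE)
}

applyPerturbation <- function(baseline, row) {
  p <- baseline
  for (f in c("thInf", "eNa", "sh", "gKdr"))
    if (!is.null(row[[f]]) && !is.na(row[[f]])) p[[f]] <- row[[f]]
  p
}

#' Run a parameter scan and report factor triples
#'
#' Simulates the baseline once and every perturbation row, reporting the
#' factor triple of each. Non-spiking grid points are reported as failed
#' (NA factors) and excluded from fitting.
#'
#' @param conditions data.frame as from \code{\link{tableOneConditions}}
#'   (columns label, thInf, eNa, sh, gKdr, optionally comparable).
#' @param baseline baseline parameters (default \code{pvModelParams()}).
#' @return list with \code{scan} (data.frame: label, factors, spiked,
#'   comparable, hInfMidpoint) and \code{baselineTrace}.
#' @export
parameterScan <- function(conditions, baseline = pvModelParams()) {
  if (!nrow(conditions)) stop("empty perturbation grid")
  if (is.null(conditions$comparable)) conditions$comparable <- TRUE
  base <- simulatePV(baseline)
  if (!length(base@spikeTimes)) stop("baseline parameters do not spike")
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    p <- applyPerturbation(baseline, conditions[i, ])
    tr <- tryCatch(simulatePV(p), error = function(e) NULL)
    spiked <- !is.null(tr) && !is.na(tr@spikeWidth) && tr@firingRate > 0
    ft <- if (spiked) factorTriple(tr, base) else rep(NA_real_, 3)
    data.frame(label = conditions$label[i], rateFactor = ft[1],
               widthFactor = ft[2], amplitudeFactor = ft[3],
               spiked = spiked, comparable = conditions$comparable[i],
               hInfMidpoint = hInfMidpoint(p), row.names = NULL)
  })
  list(scan = do.call(rbind, rows), baselineTrace = base)
}

#' Best-fitting condition for an experimental factor triple
#'
#' Minimizes the (optionally weighted) sum of squared differences between
#' each spiking condition's factor triple and the experimental triple. Ties
#' are broken by the number of perturbed parameters, then by the total
#' absolute parameter change from baseline.
#'
#' @param scanResult result of \code{\link{parameterScan}}.
#' @param conditions the condition grid that produced it.
#' @param target experimental triple (default c(0.41, 0.71, 0.46), the
#'   printed post-injury/control interneuron ratios).
#' @param baseline baseline parameters (for delta computation).
#' @param weights per-dimension weights (default uniform).
#' @return one-row data.frame: the winning condition with its loss.
#' @export
bestFit <- function(scanResult, conditions,
                    target = c(0.41, 0.71, 0.46),
                    baseline = pvModelParams(), weights = c(1, 1, 1)) {
  sc <- scanResult$scan
  ok <- which(sc$spiked)
  if (!length(ok)) stop("no spiking conditions to fit")
  loss <- vapply(ok, function(i)
    sum(weights * (as.numeric(sc[i, c("rateFactor", "widthFactor",
                                      "amplitudeFactor")]) - target)^2),
    numeric(1))
  nPert <- vapply(ok, function(i)
    sum(!is.na(unlist(conditions[i, c("thInf", "eNa", "sh", "gKdr")]))),
    numeric(1))
  totDelta <- vapply(ok, function(i) {
    row <- conditions[i, ]
    sum(vapply(c("thInf", "eNa", "sh", "gKdr"), function(f)
      if (is.na(row[[f]])) 0 else abs(row[[f]] - baseline[[f]]),
      numeric(1)))
  }, numeric(1))
  ord <- order(loss, nPert, totDelta)
  win <- ok[ord[1]]
  cbind(sc[win, , drop = FALSE],
        loss = loss[ord[1]], nPerturbed = nPert[ord[1]])
}
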