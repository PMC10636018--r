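---
title: "Methods: laminar hippocampal electrophysiology after concussion"
author: "laminar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar hippocampal electrophysiology after concussion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminar)
```

# The scientific problem

Concussion (mild traumatic brain injury) in a large-animal model alters
hippocampal CA1 physiology: putative interneurons lose firing rate, spike
width and spike amplitude while pyramidal cells are largely spared;
pyramidal cells decouple from local gamma oscillations; and the network
shows hyperexcitability (sustained depolarizing shifts, synchronized 6–8 Hz
rhythmic spikes). A biophysical model of the fast-spiking PV⁺ basket cell
attributes the interneuronal triad of changes to a single lesion: a
hyperpolarizing shift of sodium-channel steady-state inactivation.

This package implements that analysis chain as reusable, tested functions.
Because the original recordings are not public, a synthetic-data module
generates laminar LFP and phase-locked spike trains with known ground truth,
and every downstream stage is validated against that ground truth or against
analytic oracles.

# Single-unit metrics

* **Firing rate** — spikes per second over the recording. Units with zero
  spikes are excluded upstream (they warn and propagate as exclusions, not
  0 Hz rows).
* **Autocorrelogram** — ordered spike pairs binned at 1 ms into lags
  1–50 ms (lag ℓ collects differences in (ℓ−0.5, ℓ+0.5] ms), normalized to a
  probability distribution. Its **first moment** Σ ℓ·acg[ℓ] separates bursty
  (small) from tonic (large) firing; a flat autocorrelogram has first moment
  25.5 ms.
* **Spike amplitude** — |extremum − baseline|. *Baseline* is not defined in
  the source description; we use the mean of the first quarter of the
  waveform window (the pre-deflection segment). The extremum is the sample
  of maximal absolute deviation — extracellular somatic spikes are
  trough-dominant, and the amplitude is reported unsigned.
* **Spike width** — time between the two crossings of baseline ±
  amplitude/2 flanking the extremum, linearly interpolated between samples
  for sub-sample precision at 32 kHz-equivalent resolution.
* **Wavelet high-pass** — multilevel (default level 6) Daubechies-4
  decomposition with the coarsest approximation zeroed before
  reconstruction; used to remove low-frequency content from wideband traces
  with minimal waveform distortion. No wavelet package is available in the
  target environment, so the periodized transform is implemented directly;
  its analysis operator is orthonormal (perfect reconstruction is tested).

The same width/amplitude operators are applied to the biophysical model's
voltage traces, so experimental and simulated factor ratios share one
definition.

# Classification

Three ordered rules, replicating the manual procedure:

1. **Anatomical gate.** Units whose max-amplitude channel lies below the
   annotated pyramidal layer are putative dentate cells and are excluded.
   Units without a layer label cannot be gated and become unclassifiable.
2. **Rate threshold.** Rate ≤ 7 Hz → pyramidal; > 7 Hz → interneuron (the
   boundary itself is pyramidal, "7 Hz or below").
3. **Autocorrelogram guard.** The original procedure also consulted the
   first moment and waveform symmetry to "manually place" ambiguous cells,
   without a stated rule. Our determinization: calls within ±1 Hz of the
   boundary whose first moment falls on the wrong side of the candidate
   population median are set unclassifiable. This reproduces the existence
   of an unclassifiable category conservatively and deterministically; the
   guard band and threshold are arguments.

The automated cross-check is k-means (k = 2) on z-scored (log rate, width,
first moment) features. The features are the ones the manual rules consult;
standardization and initialization are not specified in the source, so we
initialize at the lowest- and highest-rate units and run Lloyd iterations,
making the labeling deterministic and order-invariant. The cluster with the
higher mean rate is the interneuron cluster. A mean silhouette below 0.35
flags populations without two real clusters: forced splits of unimodal
fixtures measure ≈ 0.21–0.26 (the classical "no substantial structure"
region), genuinely bimodal fixtures ≈ 0.76.

# Spike–LFP entrainment

Phase extraction is a zero-phase FFT band-pass followed by the
analytic-signal argument (0 at the oscillation peak, +π/2 a quarter cycle
later). The source names the statistic (mean vector length) but not the
phase-extraction method; ours is documented and swappable. The MVL of a
phase set is the modulus of the mean unit vector; under uniform phases its
expectation is ≈ √(π/(4n)), which is the chance floor against which profiles
must be read — weak locking (resultant ~0.02) is only resolvable with
thousands of spikes.

The band grid is contiguous: 1 Hz bins below 12 Hz, 5 Hz bins from 12 to
302 Hz, so reported ranges such as 4–6 Hz and 62–82 Hz are unions of whole
bins. Whether the original ranges came from a pre-set grid or post-hoc
merging is unstated; we merge contiguous significant bins (two-sided
Mann-Whitney, α = 0.05) and say so. Spikes within one filter transient
(1/bandwidth, at least 0.1 s) of the recording edges are dropped from each
band's pool. No MVL bias correction is applied (raw MVL is reported and
group sizes are comparable).

# Spectral analysis and event detection

* **Layer localization**: per-channel RMS of the 600–6000 Hz band (a proxy
  for spiking activity); requires ≥ 12 kHz wideband input. Flat profiles
  (max/median < 1.5) are flagged non-informative.
* **PSD**: Welch with 2 s Hann windows and 50% overlap (the source does not
  print estimator parameters; these are arguments), density-scaled so the
  integral recovers the variance (Parseval, tested at ±5%).
* **Group comparison**: one curve per animal (log₁₀ power averaged over its
  deduplicated unit-bearing channels), z-scored along the frequency axis,
  per-frequency two-sample t-tests at α = 0.01, contiguous significant bins
  merged. The z-scoring axis (per curve, after animal averaging) is our
  documented choice. Mains noise "removed manually" in the source becomes a
  deterministic rule: 58–62 Hz is masked from testing and linearly
  interpolated in curves. The per-frequency tests are reported without
  multiple-comparison correction, as in the source; this is flagged here
  explicitly. Note one side effect of z-scoring: lowering power in one band
  raises the rest of the curve relatively, so bins away from a manipulated
  band can show the opposite direction.
* **Detectors**: the phenomena are described qualitatively ("over 1 s",
  "6–8 Hz", "across all laminar layers"); the algorithms are ours and their
  constants are calibration parameters. Sustained depolarization: < 2 Hz
  low-pass, rolling-median baseline (20 s; computed on a 20 Hz decimated
  copy), deflection below −5 MAD on ≥ 75% of channels for ≥ 1 s. Rhythmic
  spikes: smoothed 6–8 Hz analytic envelope above median + 5 MAD on ≥ 75% of
  channels for ≥ 3 cycles — a band-power criterion, so co-elevated but
  phase-scrambled activity is still detected (documented behavior). Both
  refine onset/offset at 50% of the event's peak on the cross-channel median
  trace, which centers the estimate on the true edge despite filter
  smoothing; at default thresholds the false-positive rate on clean
  synthetic background is 0 events per 100 s across 20 seeds.

# The fast-spiking interneuron model

A single-compartment Hodgkin-Huxley-type model (leak + Na m³h + delayed
rectifier n⁴; Boltzmann steady states; bell-shaped voltage-dependent time
constants; fixed-step RK4) replaces the cited multi-compartment basket-cell
model. The substitution removes a heavyweight simulator dependency while
preserving the mechanistic claim under test — that a hyperpolarizing h∞
shift jointly reduces rate, width and amplitude — at the cost that the
published numeric factor entries are directional, not exact, targets, and
that dendrite-specific perturbation rows can only be mapped to whole-cell
perturbations (they are flagged non-comparable in the scan report).

**Midpoint conventions.** The scan parameter `thInf` and the plotted h∞
midpoint differ by a fixed offset in the source model's parameterization,
which is not printed. We adopt: plotted midpoint = `thInf` + 14.5 mV (+
`sh`), so baseline `thInf` = −49.5 ↔ midpoint −35 mV and the best-fit
`thInf` = −59 ↔ midpoint −44.5 mV. Both numbers are exposed
(`hInfMidpoint()`).

**Constants.** Slopes and time constants are not printed in the source;
defaults (mV, ms, mS/cm²): m∞ midpoint −35, slope 6, τ_m ≤ 0.03; h∞ slope 7,
τ_h ≤ 0.8; n midpoint −30, slope 6, τ_n ≤ 0.4; g_Na = 100, g_K = 25,
E_Na = +55, E_K = −90, leak 0.1 at −65. These were tuned once to the
qualitative contract and then frozen. Two choices deserve comment:

* *Very fast potassium kinetics.* For the width factor to fall along with
  the amplitude factor, the repolarization slope must be an (almost)
  instantaneous function of voltage: then a smaller spike traverses its
  half-width proportionally faster. With slow, history-dependent K
  activation, smaller spikes recruit less K, repolarize slower, and the
  width factor rises above 1 in every regime we tried — the opposite of the
  observation. Real fast-spiking cells achieve voltage-locked repolarization
  with Kv3-family channels; the fast τ_n plays that role here.
* *Stimulus.* The injection protocol is not printed. Rule (frozen): the
  smallest value on a 0.1 µA/cm² grid giving repetitive firing ≥ 5 Hz at
  baseline — 0.7 µA/cm², giving a 30 Hz baseline typical of anesthetized
  fast-spiking units.

**Features.** Spike detection is an upward 0 mV crossing with 1 ms lockout.
The steady-state rate uses the mean inter-spike interval over the analysis
window (stimulus onset + 100 ms to stimulus end): a count-based rate
quantizes factor ratios at the few-percent level, while the ISI-based rate
resolves the monotone trends the scan reports. Width and amplitude come from
the mean aligned waveform through the same operators as experimental
waveforms.

**Window current.** Overlap of activation and inactivation is quantified as
∫ min(m∞, h∞) dV over −100…+20 mV (trapezoid rule; the source says "area
under the curves" without a formula). Under the −35 → −44.5 mV shift with
m∞ fixed the area strictly decreases; the relative decrease is
slope-dependent and is therefore regression-locked to the package's own
numeric oracle (0.4328 with the defaults above) rather than asserted against
the published ~30–33%, which was produced by unpublished slope constants.

**Fit.** `bestFit()` minimizes the sum of squared differences to the
experimental triple (0.41, 0.71, 0.46), breaking ties by fewest perturbed
parameters, then smallest total |Δ|. On the published condition grid our
model selects `thInf = −60` with `thInf = −59` a near-tie — both
single-parameter h-inactivation shifts, so the mechanistic conclusion (an
h∞ shift alone fits best) is reproduced even though the winning grid point
differs by one step. The amplitude factor is the worst-fit dimension here as
in the original (our 0.95 and their 0.73, versus 0.46 observed); fit weights
are uniform by default and configurable.

# The synthetic stated world

Generator defaults encode the study's printed statistics; where nothing is
printed, values were chosen once as field-typical and are listed here.

* Probe: 32 channels, 100 µm spacing; LFP at 2 kHz; 600 s default duration
  (at which configured rates are recovered within 5%). The top half of the
  probe is annotated as the pyramidal layer.
* Class rates (lognormal, truncated): control pyramidal mean 2.27 Hz,
  interneuron 7.46 Hz; post-injury 1.70 and 3.09 Hz. Control classes are
  truncated on opposite sides of 7 Hz, matching the classification rule;
  post-injury interneurons are *not* (their printed mean lies below 7 Hz —
  the same tension exists in the source's own rule set).
* Waveforms: class templates at the printed amplitude/width means (control
  256 µV / 0.336 ms pyramidal, 367 µV / 0.373 ms interneuron; post-injury
  238/0.280 and 170/0.263), as a negative Gaussian trough (FWHM = width)
  plus a small after-wave, sampled at 32 kHz; ±5% per-unit jitter.
* Locking: von Mises concentrations chosen so the population resultant
  I₁(κ)/I₀(κ) equals the printed entrainment means — pyramidal 62–82 Hz
  κ = 0.040/0.010 (control/post = resultants 0.020/0.005), 103–117 Hz
  κ = 0.036/0.006, interneuron 4–6 Hz κ = 0.026/0.082 (0.013/0.041).
* Oscillators: 5 Hz (150 µV, deep), 55 and 72 Hz gamma, 110 and 150 Hz
  high-frequency (pyramidal-layer centered, Gaussian depth profiles);
  post-injury gamma and high-frequency amplitudes are reduced 40%.
  Background is 1/f (exponent 1, 100 µV RMS).
* Burstiness: pyramidal units are burst-renewal processes (geometric burst
  length, mean 3; 5 ms intra-burst ISI, 0.5 ms jitter); interneurons are
  tonic. These are free parameters, not calibrated claims — per-class ISI
  statistics for pig CA1 are not published.
* Spike generation is exact point-process thinning against the analytic
  oscillator phase, so phase-locked trains have *exactly* the intended
  stationary intensity λ(t) = r·exp(κ cos(φ(t)−φ₀))/I₀(κ): the mean rate
  stays r and the expected MVL is the Bessel ratio. No refractory pruning is
  applied — it would preferentially delete preferred-phase spikes and bias
  the MVL calibration (only exact ties are dropped to keep spike times
  strictly increasing).
* One RNG stream per unit, derived from the master seed by stable hashing,
  so adding units never perturbs existing ones; output is bit-identical
  under a fixed seed.

What the generator does **not** emulate: biophysical forward models of
extracellular fields, spike-sorting confusion (overlaps, drift), anesthesia
state changes, non-stationary oscillations, or animal-to-animal
heterogeneity beyond independent noise seeds. A green test therefore
establishes that the estimators recover the statistics they target under the
stated model, not that the pipeline is robust to real-recording artifacts.

# Numerical choices and degenerate inputs

* FFT brick-wall filters are zero-phase by construction; band edges beyond
  Nyquist are errors. Analytic-signal phase is interpolated linearly in the
  complex plane at spike times.
* ACG with no pair within 50 ms returns all zeros; its first moment is NA
  with a warning. Fewer than 2 spikes is an error.
* Flat waveforms (amplitude 0) and half-levels not crossed on both flanks
  are errors, not NA.
* The RK4 step (0.01 ms) halves to < 1% feature change; |V| > 200 mV aborts
  with an integration-failure error.
* k-means ties in initialization (all-equal features) are broken by an
  epsilon perturbation; constant features carry no information and are
  zeroed after standardization.
* Mann-Whitney uses the exact distribution where R's implementation permits
  (small n, no ties); identical groups return the maximal attainable p.
* The report builder treats missing stages as explicit gaps, never silent
  omissions; reruns with the same seeds are byte-identical.

# Known limitations

* The single-compartment model reproduces directions and the rate factor
  well, the width factor approximately, and the amplitude factor only
  weakly (see above); conclusions about amplitude rest on the experimental
  triple, not the model.
* Entrainment at the study's printed magnitudes (~0.02) is close to the
  chance floor for realistic spike counts; group comparisons at those
  magnitudes need thousands of spikes per unit, which the generator can
  provide but short recordings cannot.
* Per-frequency significance ranges are reported without multiple-comparison
  correction, as in the source; treat the merged ranges as descriptive.
* The velocity-dose ANOVA example at the printed subgroup moments yields a
  jointly significant-and-monotone outcome in ≈ 82% of simulations — the
  stated world is near the edge of that criterion, and the tests document
  the measured rate rather than a rounder aspiration.
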