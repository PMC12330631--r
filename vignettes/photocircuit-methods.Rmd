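---
title: "Models and methods in photocircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in photocircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocircuit)
```

photocircuit bundles four analysis layers around one scientific question:
how plasticity of ventral-hippocampal (vHPC) input to medial prefrontal
cortex (mPFC) reshapes the VIP–SST–PV disinhibitory interneuron motif, and
how that reorganization reads out in fiber photometry and in spatial
working-memory behavior. This vignette explains the models, their
assumptions, the tunable parameters, and the numerical choices — including
the places where the design was genuinely open and what we chose.

## 1. The microcircuit model

The network is a 36-neuron leaky integrate-and-fire circuit: 4 VIP, 6 SST
and 6 PV interneurons and 20 pyramidal cells, driven by an external vHPC
event process. Each neuron's membrane potential decays geometrically with
`vdecay = exp(-dt/tau_m)` (`tau_m` = 10 ms, `dt` = 0.1 ms) and integrates,
scaled by `dt`, the weighted synaptic outputs of its input classes:
inhibition from VIP, SST and PV class outputs; excitation from pyramidal
AMPA- and NMDA-like outputs (NMDA scaled by 0.3); the vHPC drive (AMPA +
0.3·NMDA + background noise); and a private noise term. Crossing the
threshold (10) emits a spike and forces the voltage to −10 on the *next*
step. Class outputs decay with `exp(-dt/tau_syn)` (20 ms for interneurons,
10/80 ms for pyramidal AMPA/NMDA) and increment by the fraction of the
class that fired; pyramidal cells additionally carry per-cell outputs
routed through a random 20×20 connectivity matrix (connection probability
0.2, no self-connections). All weights live in a 5×4 matrix
(`defaultWeightMatrix()`); the pyramidal source row is (0.8, 8, 0.8, 0.25)
onto (VIP, SST, PV, PYR) — the only four-value reading of the published
row, with the unusually large PYR→SST value kept as a configurable default
rather than a hard-coded constant.

The vHPC drive is an event raster: rate 0 before 2 s, 100 Hz during the
2–3-s stimulation window, and an exponential decay (tau 1 s) afterwards.
Events are Bernoulli per step with `p = rate·dt` (at most one event per
step; configurations with `rate·dt > 1` are rejected as undersampled).
Each event contributes a truncated exponential kernel — amplitude 1, tau
8 ms over 40 steps for the AMPA component, tau 80 ms over 400 steps for
NMDA. Background vHPC noise (100 Hz throughout) and per-neuron noise
(100 Hz, amplitude 1, 1.2 for PV) use the AMPA-like kernel.

Numerical choices worth knowing:

* **Reset semantics.** A neuron that fires at step *t* is clamped to the
  reset value at *t* + 1 (its inputs at that step are ignored) and
  integrates normally from *t* + 2. The source material states the reset
  but not the input handling; clamping is the simplest deterministic rule.
* **Kernel filtration.** The truncated exponential convolution is applied
  through its exact O(n) recursion `y[t] = d·y[t−1] + x[t] − d^L·x[t−L]`,
  implemented in compiled code; a brute-force convolution oracle in the
  test suite pins the equivalence.
* **Two engines.** `runSimulation()` uses a compiled (Rcpp) stepping core;
  `stepNetwork()`/`runSimulationReference()` is a pure-R per-step
  reference with identical update order. The suite asserts agreement to
  1e-9 on spiking and non-spiking regimes — with discrete spiking
  dynamics, any implementation divergence amplifies, so this is a strong
  equivalence check.
* **Smoothing.** Spike-count traces are smoothed with a Gaussian kernel
  (sigma 25 ms, truncated at ±4 sigma, FFT convolution); near the record
  edges the kernel is renormalized over its in-range support so the
  smoother stays an average and total activity mass is preserved.
* **Evoked peaks.** Baseline is the mean activity over 0.1–2 s; the
  response window defaults to stimulation onset through the end of the
  simulation (no narrower window is published for the peak summary).

The weight-sweep experiment (`runWeightSweep()`) lowers the vHPC→VIP
weight from 1.6 to 0.85 over a six-point evenly spaced grid (only the
endpoints are published; the grid is configurable), runs 10 simulations of
5 runs each per weight, and summarizes per-class evoked peaks as mean ±
SEM. `monotonicitySummary()` reports the Spearman correlation between
weight and mean peak per class; the expected pattern — VIP, PV and PYR
positive, SST negative — is the disinhibitory signature: weakening
vHPC→VIP disinhibits SST, which in turn suppresses PV and pyramidal
responses. Per-simulation seeds are drawn from a master seed so the whole
sweep is reproducible. The acceptance checks run a scaled sweep (5
simulations per weight) to stay within desk-scale runtimes.

## 2. The photometry chain

The processing chain mirrors spectrometer-based photometry: photon counts
per wavelength (350–1130 nm in the real instrument; the synthetic grid is
400–700 nm) at 20 or 40 Hz.

* `bandSummedSignal()` sums the closed bands 500–541 nm (GCaMP) and
  577–618 nm (tdTomato).
* `linearUnmix()` solves per-frame ordinary least squares against
  unit-norm reference spectra plus a constant background column. The
  published analysis cites an unmixing algorithm whose constraint choice
  is not printed; OLS is the default and a non-negativity option exists.
* `detrendLinear()` removes a fitted line and adds back the mean, so
  fading is removed without destroying the scale that ratios and dF/F
  need.
* `downsampleMean()` block-averages (40→10, 20→10 Hz) rather than
  decimating, acting as a crude anti-alias filter.
* `dffPerTrial()`/`peakResponse()` implement percent dF/F against the
  10-s pre-stimulation baseline and the 10–15-s peak window.
* `ratioZscoreTrials()` forms GCaMP/tdTomato and z-scores within each
  trial. Any per-frame multiplicative artifact shared by the two channels
  cancels exactly in the ratio — the generator's motion artifact is
  deliberately of this form so the invariant is testable exactly. Trials
  with a near-zero denominator or zero variance are excluded with a
  warning, never imputed.
* Window operations (`distalDelayScore()`, `periEventAverage()`) snap
  event times to the nearest 10-Hz sample; the distal-delay score is the
  mean z over `[choice_start − 2 s, choice_start)`.
* `crosscorrLagged()` computes Pearson correlations at integer lags up to
  ±50 samples (±5 s at 10 Hz); positive lags mean calcium leads velocity.

### Transient detection

`detectTransients()` finds significant calcium events with the published
parameters: threshold multiplier 2.91 (which is
`qnorm(0.975)/qnorm(0.75)` to two decimals, so the MAD is used *unscaled*
— the Gaussian consistency factor is folded into the multiplier), widths
0.5–10 s, minimum separation 1 s. The original analysis's peak-finding
parameter semantics are not recoverable from the text, so the
interpretation is isolated behind `TransientParams`. We evaluated
topographic prominence (the scipy-style reading) and found it structurally
incompatible with a low false-event rate on pure noise: the tallest peak
of any noise segment has large prominence relative to distant minima, and
both our implementation and `scipy.signal.find_peaks` produce ~0.2–0.5
spurious events per 10 s of white noise at that threshold. The adopted
semantics measure an event's **magnitude above the series median** (a
robust baseline — matching the definition of event magnitude as signal
units above baseline) and its **width at half magnitude**; a
threshold-crossing noise sample is essentially never flanked by the ≥0.5-s
sustained elevation the width band demands, so the pure-noise false-event
rate is near zero while recall on generated events exceeds 0.95. Peaks
whose half-magnitude supports overlap are merged (one contiguous elevation
is one event), which prevents double-counting the decay shoulder of
compound events. `spontaneousStats()` applies the detector per 2.5-min bin
of a 10-min baseline and normalizes to a reference (first) day.

## 3. Functional regression

Trial-level z-scored signals `Y` (trials × timepoints) are modeled
per-timepoint with the five published fixed-effect structures
(`modelSpec(1:5)`): stimulation; outcome; training × outcome; training ×
stimulation; training × genotype. Training is continuous in [0, 1] (first
to last trial per mouse); outcome (incorrect = 1), stimulation (HFS = 1)
and genotype (mutant = 1) are 0/1.

Estimation deviates deliberately from a full functional mixed-model
likelihood: point estimates are pointwise ordinary least squares, and all
cluster-level (mouse) uncertainty — including what a random intercept or
outcome slope would absorb — enters through a cluster bootstrap
(`clusterBootstrapCI()`). The random-effect covariance is never estimated
explicitly; it is a deliberately unhoused quantity under this scheme.

The interval construction was the one genuinely open design point, and the
null-calibration simulation settled it. Raw percentile intervals over
replicate coefficients under-cover at this design's cluster count: with 12
mice, between-group contrasts behave like t statistics with roughly 5–11
degrees of freedom, and measured coverage was 87–92% across terms —
exactly `2·P(T_df < 1.96) − 1`. The pointwise intervals therefore use the
**cluster bootstrap-t**: each replicate's coefficient deviation is
studentized by that replicate's cluster-robust (CR0) standard error, and
the interval is `betahat − q_{97.5/2.5}(pivots)·se0`. Measured null
coverage under the default cohort (12 mice × 100 trials, 200 replicates)
is 94–97% per term. Joint bands use the max-statistic construction — the
95th percentile of each term's maximum over time of the replicate
deviation studentized by the bootstrap SD — because the max of ~100
correlated t-tailed pivots is far too heavy for useful power, while the
SD-studentized max statistic localizes injected window effects reliably.
Joint bands are widened where necessary so they always contain the
pointwise bands; `significantIntervals()` reports the signed maximal runs
where the joint band excludes zero.

Degenerate bootstrap replicates (a single distinct cluster, or a
rank-deficient design) are redrawn with a bounded retry count and a
message.

## 4. Behavior

`daysToCriterion()` applies the delayed non-match-to-sample rule: 10
trials/day until three consecutive days at ≥70% correct, capped at 15
days. "Days to criterion" reports the day *completing* the three-day run
(a mouse perfect from day 1 scores 3); the published convention is not
printed, so this is fixed here and documented. Mice that never reach
criterion are right-censored at the cap with `reached = FALSE`.
`earlyLateSplit()` takes the first and final `floor(n/3)` trials;
`correlateWithAccuracy()` is a plain Pearson correlation of per-mouse
distal-delay scores against overall training accuracy (all training days
by default — whether the original used pre-criterion days only is not
printed, and the choice is switchable by subsetting the record).

## 5. The synthetic-data generator

The generator (`generatorParams()`, `simulateSwmSession()`,
`simulateStimDay()`, `simulateCohort()`, `makeSpontaneousTrace()`)
produces every input the pipelines consume, with ground truth attached.
Its defaults are the study conditions: 6 mice per group, 100 trials per
mouse (10 per training day), 20-Hz task acquisition (40 Hz for
stimulation days), exactly 10-s delay epochs, and a 10-s peri-choice
analysis window at 10 Hz (100 timepoints, −8 to +1.9 s around Choice
Start) with the distal-delay window as its final 2 s before the event.

Choices that define what the generator does and does not emulate:

* **Transient kinetics.** A difference-of-exponentials kernel (rise
  50 ms, decay 500 ms) as a GCaMP6f-like default; indicator kinetics are
  not modeled beyond this.
* **Spontaneous events are compound.** Population photometry transients
  reflect bursts of coincident activity, not single action potentials; an
  event is 3 + Poisson(4) kernels stacked 100 ms apart with a shared
  lognormal amplitude (meanlog log 3, sdlog 0.3, z-like units), at a
  hard-core rate (0.1 Hz, minimum 2-s separation). This places event
  half-magnitude widths (~0.6–1.5 s) inside the 0.5–10-s band the event
  analysis treats as admissible — a generator emitting events at the edge
  of that band would not emulate the data the analysis assumes.
* **Noise color.** The fast residual noise of spontaneous traces is
  white, because frame-to-frame variability in photometry is photon shot
  noise. Trial-level cohort residuals are instead smooth (0.2-s Gaussian
  filtered, unit SD), modeling slow physiological fluctuation of z-scored
  signals.
* **Optics.** Both fluorophores are mixed through Gaussian reference
  spectra (peaks 513/581 nm, SD 12 nm — most of each profile's mass falls
  in its summation band), multiplied by a *shared* slow multiplicative
  motion artifact (5%, 10-s timescale) and a linear bleach (20% per
  session), then Poisson-sampled. Sharing the artifact across channels is
  deliberate: it makes the ratio method's core assumption exactly true,
  so the cancellation invariant is testable exactly rather than
  approximately.
* **Effects and behavior.** Injected distal-delay shifts are additive
  constants over the distal window composed from group, outcome, training
  and training-by-group terms plus a per-mouse random intercept (SD 0.3).
  Outcomes are Bernoulli with a logistic link that improves with training
  and, when coupling is enabled, worsens with the trial's pre-outcome
  distal activity — making the distal-score-to-accuracy correlation
  controllable in sign.
* **Velocity** is a lagged linear readout of the calcium truth (negative
  gain and calcium leading by 0.5 s in the VIP-like default) plus white
  noise, floored at zero.

What passing tests on this generator do *not* show: robustness to
hemodynamic or wavelength-dependent artifacts (the motion artifact here is
exactly shared), to non-Poisson detector noise, to non-stationary event
statistics within a session, or to delay epochs of variable length. Those
are outside the generator by design.

## 6. Problem sizes and reproducibility

Every stochastic function takes an explicit seed, and derived seeds are
drawn from a master seed so sweeps and cohorts are reproducible end to
end. The simulation studies in the test suite use these sizes, chosen to
pin each property with comfortable statistical margin at desk scale: the
directional weight sweep runs 5 simulations × 5 runs per weight over the
six-point grid; detector operating characteristics use 20 ten-minute
sessions plus 200 ten-second pure-noise segments; null calibration of the
regression bands uses 200 cohorts of 12 × 100 trials with 200 bootstrap
replicates each, effect recovery 100 cohorts for bias (point estimates
suffice there) and 25 bootstrap-fitted cohorts for joint-band power; the
engine-equivalence oracle runs 1,000 steps in spiking and non-spiking
regimes.
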