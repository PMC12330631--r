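#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

CELL_CLASSES <- c("VIP", "SST", "PV", "PYR")
WEIGHT_SOURCES <- c("vHPC", "VIP", "SST", "PV", "PYR")

#' NetworkConfig: parameters of the prefrontal microcircuit model
#'
#' Holds every constant of the 36-neuron leaky integrate-and-fire model of the
#' mPFC VIP-SST-PV-pyramidal microcircuit driven by stochastic vHPC input:
#' cell counts, the 5x4 synaptic weight matrix (sources vHPC, VIP, SST, PV,
#' PYR onto targets VIP, SST, PV, PYR), membrane and synaptic time constants,
#' spiking threshold/reset, the integration grid, the stimulation protocol,
#' and the noise model. Weights are stored non-negative; inhibitory signs are
#' applied by the voltage update rule.
#'
#' @slot nCells named integer, neurons per class (VIP, SST, PV, PYR).
#' @slot weights 5x4 non-negative matrix, `weights[source, target]`.
#' @slot tauMembraneMs membrane time constant (ms).
#' @slot tauSynMs named numeric, synaptic decay time constants (ms) for the
#'   five output channels VIP, SST, PV, PYR_AMPA, PYR_NMDA.
#' @slot nmdaScale scale factor applied to NMDA-channel outputs.
#' @slot spikeThreshold,resetValue firing threshold and post-spike reset (model units).
#' @slot dtMs,durationS integration step (ms) and total simulated time (s).
#' @slot stimWindowS length-2 numeric, vHPC stimulation window (s).
#' @slot stimRateHz expected vHPC event rate during stimulation (Hz).
#' @slot postStimDecayTauMs time constant of the post-stimulation rate decay (ms).
#' @slot vhpcKernel,vhpcNmdaKernel named numeric `c(tau_ms=, length_steps=)`,
#'   exponential kernels applied to the vHPC event raster for the AMPA and
#'   NMDA components.
#' @slot vhpcNoiseRateHz rate of background vHPC noise events (Hz).
#' @slot neuronNoise list with `rate_hz`, `amplitude` (named per class),
#'   `tau_ms`, `length_steps`: the per-neuron noise event model.
#' @slot pyrConnectionProb probability of a connection between two pyramidal cells.
#' @slot smoothingSigmaMs Gaussian smoothing sigma for activity traces (ms).
#' @exportClass NetworkConfig
setClass("NetworkConfig", representation(
  nCells = "integer",
  weights = "matrix",
  tauMembraneMs = "numeric",
  tauSynMs = "numeric",
  nmdaScale = "numeric",
  spikeThreshold = "numeric",
  resetValue = "numeric",
  dtMs = "numeric",
  durationS = "numeric",
  stimWindowS = "numeric",
  stimRateHz = "numeric",
  postStimDecayTauMs = "numeric",
  vhpcKernel = "numeric",
  vhpcNmdaKernel = "numeric",
  vhpcNoiseRateHz = "numeric",
  neuronNoise = "list",
  pyrConnectionProb = "numeric",
  smoothingSigmaMs = "numeric"
))

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (!identical(names(object@nCells), CELL_CLASSES) || any(object@nCells < 1L))
    msg <- c(msg, "nCells must be positive counts named VIP, SST, PV, PYR")
  w <- object@weights
  if (!identical(dim(w), c(5L, 4L)) ||
      !identical(rownames(w), WEIGHT_SOURCES) ||
      !identical(colnames(w), CELL_CLASSES))
    msg <- c(msg, "weights must be a 5x4 matrix with sources vHPC,VIP,SST,PV,PYR and targets VIP,SST,PV,PYR")
  else if (any(!is.finite(w)) || any(w < 0))
    msg <- c(msg, "weights must be finite and non-negative")
  pos <- c(tauMembrane = object@tauMembraneMs, object@tauSynMs,
           dt = object@dtMs, duration = object@durationS,
           postStimTau = object@postStimDecayTauMs,
           smoothSigma = object@smoothingSigmaMs)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all time constants, dt, duration and sigma must be strictly positive")
  if (!identical(names(object@tauSynMs), c("VIP", "SST", "PV", "PYR_AMPA", "PYR_NMDA")))
    msg <- c(msg, "tauSynMs must be named VIP, SST, PV, PYR_AMPA, PYR_NMDA")
  if (object@stimRateHz < 0 || object@vhpcNoiseRateHz < 0)
    msg <- c(msg, "event rates must be non-negative")
  sw <- object@stimWindowS
  if (length(sw) != 2L || sw[1] >= sw[2] || sw[1] < 0 || sw[2] > object@durationS)
    msg <- c(msg, "stimWindowS must be an increasing interval inside [0, durationS]")
  if (object@nmdaScale < 0 || object@nmdaScale > 1)
    msg <- c(msg, "nmdaScale must lie in [0, 1]")
  p <- object@pyrConnectionProb
  if (!is.finite(p) || p < 0 || p > 1)
    msg <- c(msg, "pyrConnectionProb must lie in [0, 1]")
  vd <- exp(-object@dtMs / object@tauMembraneMs)
  if (!(vd > 0 && vd < 1))
    msg <- c(msg, "exp(-dt/tauMembrane) must lie in (0, 1)")
  for (k in list(object@vhpcKernel, object@vhpcNmdaKernel))
    if (!identical(names(k), c("tau_ms", "length_steps")) || k[1] <= 0 || k[2] < 1)
      msg <- c(msg, "kernels must be c(tau_ms = >0, length_steps = >=1)")
  nn <- object@neuronNoise
  if (!all(c("rate_hz", "amplitude", "tau_ms", "length_steps") %in% names(nn)) ||
      !identical(names(nn$amplitude), CELL_CLASSES))
    msg <- c(msg, "neuronNoise must list rate_hz, amplitude (per class), tau_ms, length_steps")
  if (length(msg)) msg else TRUE
})

#' SimulationOutput: recorded activity of one network run
#'
#' Per-class spike-count timeseries (spikes summed over the neurons of each
#' class at every integration step) together with the Gaussian-smoothed
#' photometry-like activity traces derived from them.
#'
#' @slot spikeCounts 4 x steps matrix of non-negative integers (rows VIP, SST, PV, PYR).
#' @slot activity 4 x steps matrix, `spikeCounts` smoothed with a Gaussian
#'   kernel (sigma from the configuration, edge-renormalized).
#' @slot time numeric vector of step times (s).
#' @slot seed integer seed the run was generated from.
#' @slot configHash hash of the generating [NetworkConfig-class].
#' @exportClass SimulationOutput
setClass("SimulationOutput", representation(
  spikeCounts = "matrix",
  activity = "matrix",
  time = "numeric",
  seed = "integer",
  configHash = "character"
))

setValidity("SimulationOutput", function(object) {
  msg <- character()
  if (!identical(rownames(object@spikeCounts), CELL_CLASSES))
    msg <- c(msg, "spikeCounts rows must be VIP, SST, PV, PYR")
  if (any(object@spikeCounts < 0) ||
      any(object@spikeCounts != round(object@spikeCounts)))
    msg <- c(msg, "spikeCounts must be non-negative integers")
  if (!identical(dim(object@spikeCounts), dim(object@activity)))
    msg <- c(msg, "activity must have the shape of spikeCounts")
  if (ncol(object@spikeCounts) != length(object@time))
    msg <- c(msg, "time grid must match the number of steps")
  if (length(msg)) msg else TRUE
})

#' ActivityTrace: run-averaged smoothed activity
#'
#' Element-wise mean of the smoothed activity traces over several independent
#' runs of the network under one configuration (the model's "simulation").
#'
#' @slot activity 4 x steps matrix of mean smoothed activity.
#' @slot time step times (s).
#' @slot nRuns number of runs averaged.
#' @slot seeds integer seeds of the individual runs.
#' @slot configHash hash of the generating configuration.
#' @exportClass ActivityTrace
setClass("ActivityTrace", representation(
  activity = "matrix",
  time = "numeric",
  nRuns = "integer",
  seeds = "integer",
  configHash = "character"
))

#' SweepResult: evoked peaks across a vHPC-to-VIP weight sweep
#'
#' @slot peaks data.frame with columns `weight`, `class`, `sim`, `peak`:
#'   one baseline-subtracted evoked peak per simulation and cell class.
#' @slot weights the descending weight grid used.
#' @slot nSims simulations per weight, @slot runsPerSim runs averaged per simulation.
#' @slot seed master seed, @slot configHash hash of the base configuration.
#' @exportClass SweepResult
setClass("SweepResult", representation(
  peaks = "data.frame",
  weights = "numeric",
  nSims = "integer",
  runsPerSim = "integer",
  seed = "integer",
  configHash = "character"
))

#' SpectralTimeseries: wavelength-by-time photon counts
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose single assay
#' `counts` is a wavelength x frame matrix of spectrometer photon counts.
#' Row metadata holds the wavelength grid (nm); `metadata()` holds the
#' acquisition rate (Hz) and session-relative start time (s).
#'
#' @exportClass SpectralTimeseries
setClass("SpectralTimeseries", contains = "SummarizedExperiment")

setValidity("SpectralTimeseries", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else if (any(SummarizedExperiment::assay(object, "counts") < 0))
    msg <- c(msg, "photon counts must be non-negative")
  wl <- SummarizedExperiment::rowData(object)$wavelength_nm
  if (is.null(wl) || any(diff(wl) <= 0))
    msg <- c(msg, "rowData wavelength_nm must be a strictly increasing grid")
  md <- S4Vectors::metadata(object)
  if (is.null(md$rate_hz) || md$rate_hz <= 0)
    msg <- c(msg, "metadata rate_hz must be positive")
  if (length(msg)) msg else TRUE
})

#' ReferenceSpectra: unit-normalized fluorophore emission profiles
#'
#' @slot wavelengths wavelength grid (nm), strictly increasing.
#' @slot spectra wavelength x fluorophore matrix; each column non-negative
#'   with unit Euclidean norm.
#' @exportClass ReferenceSpectra
setClass("ReferenceSpectra", representation(
  wavelengths = "numeric",
  spectra = "matrix"
))

setValidity("ReferenceSpectra", function(object) {
  msg <- character()
  if (any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  if (nrow(object@spectra) != length(object@wavelengths))
    msg <- c(msg, "spectra rows must match the wavelength grid")
  if (any(object@spectra < 0))
    msg <- c(msg, "reference spectra must be non-negative")
  nrm <- sqrt(colSums(object@spectra^2))
  if (any(abs(nrm - 1) > 1e-8))
    msg <- c(msg, "each reference spectrum must have unit Euclidean norm")
  if (length(msg)) msg else TRUE
})

#' TransientParams: calcium-transient detection parameters
#'
#' Parameters of baseline-referenced peak detection on 10-Hz calcium signals.
#' The default multiplier 2.91 is the two-sided 95% Gaussian quantile divided
#' by the Gaussian quartile deviation, so it is applied to the *unscaled*
#' median absolute deviation (no 1.4826 consistency factor).
#'
#' @slot madMultiplier minimum event magnitude (height above the series
#'   median) in units of MAD(signal).
#' @slot minWidthS,maxWidthS admissible half-magnitude width range (s).
#' @slot minSeparationS minimum distance between retained peaks (s).
#' @slot featureWindowS nominal scale (s) of the per-event feature
#'   measurement, kept from the published parameter set; it sets the
#'   minimum analyzable series length, while magnitude and width are read
#'   off each peak's own half-magnitude excursion.
#' @exportClass TransientParams
setClass("TransientParams", representation(
  madMultiplier = "numeric",
  minWidthS = "numeric",
  maxWidthS = "numeric",
  minSeparationS = "numeric",
  featureWindowS = "numeric"
))

setValidity("TransientParams", function(object) {
  msg <- character()
  if (object@madMultiplier <= 0) msg <- c(msg, "madMultiplier must be positive")
  if (!(object@minWidthS > 0 && object@minWidthS < object@maxWidthS))
    msg <- c(msg, "need 0 < minWidthS < maxWidthS")
  if (object@minSeparationS < 0 || object@featureWindowS <= 0)
    msg <- c(msg, "separation must be >= 0 and feature window > 0")
  if (length(msg)) msg else TRUE
})

#' FunctionalDataset: trial-level signals with covariates and clustering
#'
#' @slot Y trials x timepoints matrix of (z-scored) calcium signal.
#' @slot covariates data.frame of per-trial covariates; `training_fraction`
#'   is continuous in \[0, 1\]; `outcome` (0 = correct, 1 = incorrect),
#'   `stimulation` (0 = NS, 1 = HFS) and `genotype` (0 = WT, 1 = mutant)
#'   are 0/1 coded.
#' @slot mouse factor of cluster (mouse) ids, one per trial.
#' @slot time timepoint grid (s) of the columns of `Y`.
#' @exportClass FunctionalDataset
setClass("FunctionalDataset", representation(
  Y = "matrix",
  covariates = "data.frame",
  mouse = "factor",
  time = "numeric"
))

setValidity("FunctionalDataset", function(object) {
  msg <- character()
  n <- nrow(object@Y)
  if (nrow(object@covariates) != n || length(object@mouse) != n)
    msg <- c(msg, "covariates and mouse must have one row per trial")
  if (ncol(object@Y) != length(object@time))
    msg <- c(msg, "time grid must match the columns of Y")
  if (anyNA(object@covariates))
    msg <- c(msg, "covariates must not contain missing values")
  if (nlevels(droplevels(object@mouse)) < 2L)
    msg <- c(msg, "at least two clusters (mice) are required")
  for (v in intersect(c("outcome", "stimulation", "genotype"),
                      names(object@covariates)))
    if (!all(object@covariates[[v]] %in% c(0, 1)))
      msg <- c(msg, sprintf("covariate '%s' must be coded 0/1", v))
  if (length(msg)) msg else TRUE
})

#' ModelSpec: one of the five functional-regression model specifications
#'
#' @slot modelId integer 1-5.
#' @slot fixed formula of the fixed-effect structure.
#' @slot random character descriptor of the random-effect structure
#'   (absorbed by the clustered bootstrap, not fit directly).
#' @exportClass ModelSpec
setClass("ModelSpec", representation(
  modelId = "integer",
  fixed = "formula",
  random = "character"
))

#' FunctionalFit: pointwise coefficient functions with bootstrap bands
#'
#' @slot terms design-matrix term names.
#' @slot time timepoint grid (s).
#' @slot beta terms x timepoints matrix of pointwise least-squares estimates.
#' @slot pwLower,pwUpper pointwise 95% confidence bands (bootstrap percentiles).
#' @slot jointLower,jointUpper joint 95% bands (bootstrap max-statistic).
#' @slot boot nBoot x terms x timepoints array of bootstrap replicates.
#' @slot nBoot,seed replicate count and seed.
#' @exportClass FunctionalFit
setClass("FunctionalFit", representation(
  terms = "character",
  time = "numeric",
  beta = "matrix",
  pwLower = "matrix",
  pwUpper = "matrix",
  jointLower = "matrix",
  jointUpper = "matrix",
  boot = "array",
  nBoot = "integer",
  seed = "integer"
))

setValidity("FunctionalFit", function(object) {
  msg <- character()
  if (dim(object@boot)[1] != object@nBoot)
    msg <- c(msg, "bootstrap replicate count must equal nBoot")
  if (any(object@jointLower > object@pwLower + 1e-12) ||
      any(object@jointUpper < object@pwUpper - 1e-12))
    msg <- c(msg, "joint bands must contain pointwise bands everywhere")
  if (length(msg)) msg else TRUE
})

#' GeneratorParams: synthetic-data generator settings
#'
#' One object fixes the study conditions that every synthetic dataset
#' emulates: cohort size, photometry acquisition, optical artifact model,
#' calcium-transient kinetics, injected distal-delay effects, and the
#' velocity coupling. Defaults follow the acquisition described for the
#' spatial working-memory experiments (20-Hz spectra, 10-s delay epochs,
#' 10 trials per training day).
#'
#' @slot nMicePerGroup mice per group (NS-like vs manipulated).
#' @slot trialsPerMouse trials per mouse in cohort datasets.
#' @slot rateHz spectral acquisition rate (20 for task sessions, 40 for
#'   stimulation sessions).
#' @slot baselineCounts named numeric `c(gcamp=, tdtomato=)`: expected photon
#'   counts per frame attributable to each fluorophore at baseline.
#' @slot backgroundCounts flat per-wavelength background count level.
#' @slot bleachFrac total fractional linear signal loss across a session.
#' @slot motionAmplitude,motionTauS amplitude (fractional) and timescale (s)
#'   of the shared multiplicative motion artifact.
#' @slot transientRiseS,transientDecayS difference-of-exponentials kernel
#'   time constants of a single calcium transient.
#' @slot spontRateHz rate of spontaneous calcium events.
#' @slot spontAmpMeanLog,spontAmpSdLog lognormal per-spike amplitude parameters
#'   (z-like units).
#' @slot burstMeanExtra spontaneous events are bursts of `3 + Poisson(burstMeanExtra)`
#'   stacked transients 100 ms apart.
#' @slot minEventSeparationS hard-core minimum separation between spontaneous events (s).
#' @slot noiseSd,noiseSmoothS residual noise SD (z units) and its Gaussian
#'   smoothing timescale (s).
#' @slot randomInterceptSd SD of per-mouse random intercepts (z units).
#' @slot distalEffects named numeric `c(outcome=, training=, group=, training_x_group=)`:
#'   additive shifts (z units) injected in the distal-delay window.
#' @slot accuracyCoupling logistic coefficient linking distal-delay activity to
#'   the odds of an incorrect outcome (0 disables coupling).
#' @slot velocityGain,velocityLagS linear gain and lag (s; positive = calcium
#'   leads) coupling velocity to the calcium truth.
#' @slot delayS delay-epoch duration (s); the task fixes this at 10.
#' @exportClass GeneratorParams
setClass("GeneratorParams", representation(
  nMicePerGroup = "integer",
  trialsPerMouse = "integer",
  rateHz = "numeric",
  baselineCounts = "numeric",
  backgroundCounts = "numeric",
  bleachFrac = "numeric",
  motionAmplitude = "numeric",
  motionTauS = "numeric",
  transientRiseS = "numeric",
  transientDecayS = "numeric",
  spontRateHz = "numeric",
  spontAmpMeanLog = "numeric",
  spontAmpSdLog = "numeric",
  burstMeanExtra = "numeric",
  minEventSeparationS = "numeric",
  noiseSd = "numeric",
  noiseSmoothS = "numeric",
  randomInterceptSd = "numeric",
  distalEffects = "numeric",
  accuracyCoupling = "numeric",
  velocityGain = "numeric",
  velocityLagS = "numeric",
  delayS = "numeric"
))

setValidity("GeneratorParams", function(object) {
  msg <- character()
  if (object@nMicePerGroup < 1L || object@trialsPerMouse < 3L)
    msg <- c(msg, "need >= 1 mouse per group and >= 3 trials per mouse")
  nonneg <- c(object@baselineCounts, object@backgroundCounts, object@bleachFrac,
              object@motionAmplitude, object@spontRateHz, object@noiseSd,
              object@randomInterceptSd)
  if (any(!is.finite(nonneg)) || any(nonneg < 0))
    msg <- c(msg, "rates, counts and amplitudes must be finite and non-negative")
  if (!identical(names(object@distalEffects),
                 c("outcome", "training", "group", "training_x_group")))
    msg <- c(msg, "distalEffects must be named outcome, training, group, training_x_group")
  if (any(!is.finite(object@distalEffects)))
    msg <- c(msg, "distalEffects must be finite")
  if (object@delayS != 10)
    msg <- c(msg, "the delay epoch is fixed at 10 s by the task")
  if (object@transientRiseS <= 0 || object@transientDecayS <= object@transientRiseS)
    msg <- c(msg, "need 0 < rise < decay for the transient kernel")
  if (length(msg)) msg else TRUE
})
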