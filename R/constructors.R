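#' Default synaptic weight matrix of the microcircuit model
#'
#' Returns the baseline 5x4 synaptic weight matrix `W[source, target]` of the
#' mPFC microcircuit model. Sources are the vHPC input and the four local
#' classes; targets are the four local classes. All weights are stored as
#' non-negative magnitudes; the voltage update applies inhibitory signs for
#' VIP, SST and PV sources. The vHPC-to-VIP entry (1.6) is the one varied by
#' [runWeightSweep()].
#'
#' @return 5x4 numeric matrix with dimnames
#'   `list(c("vHPC","VIP","SST","PV","PYR"), c("VIP","SST","PV","PYR"))`.
#' @examples
#' W <- defaultWeightMatrix()
#' W["vHPC", "VIP"]  # 1.6
#' @export
defaultWeightMatrix <- function() {
  W <- rbind(
    vHPC = c(1.6, 1,   1.6,  1),
    VIP  = c(0,   1,   0.05, 0),
    SST  = c(1,   0,   0.75, 0.75),
    PV   = c(0,   0,   2.25, 2),
    PYR  = c(0.8, 8,   0.8,  0.25)
  )
  colnames(W) <- CELL_CLASSES
  W
}

#' Construct a microcircuit model configuration
#'
#' Builds a validated [NetworkConfig-class] with the model's published
#' defaults: 4 VIP + 6 SST + 6 PV + 20 pyramidal neurons, membrane tau 10 ms,
#' synaptic taus 20 ms (interneurons), 10 ms (pyramidal AMPA) and 80 ms
#' (pyramidal NMDA) with NMDA outputs scaled by 0.3, threshold 10 and reset
#' -10, dt = 0.1 ms over 10 s, vHPC stimulation at 100 Hz during 2-3 s
#' decaying afterwards with tau 1000 ms, 100-Hz background vHPC noise and
#' per-neuron noise (amplitude 1, PV 1.2), exponential event kernels of 8 ms
#' over 40 steps (AMPA-like) and 80 ms over 400 steps (NMDA-like), pyramidal
#' connection probability 0.2, and 25-ms Gaussian smoothing of activity.
#'
#' @param weights synaptic weight matrix, see [defaultWeightMatrix()].
#' @param nCells named integer vector of class sizes.
#' @param durationS,dtMs simulated duration (s) and step (ms).
#' @param stimWindowS,stimRateHz,postStimDecayTauMs stimulation protocol.
#' @param vhpcNoiseRateHz background vHPC event rate (Hz).
#' @param neuronNoise per-neuron noise model (list: rate_hz, amplitude, tau_ms,
#'   length_steps).
#' @param tauMembraneMs,tauSynMs,nmdaScale,spikeThreshold,resetValue,
#'   vhpcKernel,vhpcNmdaKernel,pyrConnectionProb,smoothingSigmaMs remaining
#'   model constants; see slot documentation.
#' @return a [NetworkConfig-class] object.
#' @examples
#' cfg <- networkConfig()
#' weights(cfg)["vHPC", "VIP"]
#' @export
networkConfig <- function(weights = defaultWeightMatrix(),
                          nCells = c(VIP = 4L, SST = 6L, PV = 6L, PYR = 20L),
                          tauMembraneMs = 10,
                          tauSynMs = c(VIP = 20, SST = 20, PV = 20,
                                       PYR_AMPA = 10, PYR_NMDA = 80),
                          nmdaScale = 0.3,
                          spikeThreshold = 10,
                          resetValue = -10,
                          dtMs = 0.1,
                          durationS = 10,
                          stimWindowS = c(2, 3),
                          stimRateHz = 100,
                          postStimDecayTauMs = 1000,
                          vhpcKernel = c(tau_ms = 8, length_steps = 40),
                          vhpcNmdaKernel = c(tau_ms = 80, length_steps = 400),
                          vhpcNoiseRateHz = 100,
                          neuronNoise = list(rate_hz = 100,
                                             amplitude = c(VIP = 1, SST = 1,
                                                           PV = 1.2, PYR = 1),
                                             tau_ms = 8, length_steps = 40),
                          pyrConnectionProb = 0.2,
                          smoothingSigmaMs = 25) {
  new("NetworkConfig",
      nCells = stats::setNames(as.integer(nCells), names(nCells)),
      weights = weights,
      tauMembraneMs = tauMembraneMs,
      tauSynMs = tauSynMs,
      nmdaScale = nmdaScale,
      spikeThreshold = spikeThreshold,
      resetValue = resetValue,
      dtMs = dtMs,
      durationS = durationS,
      stimWindowS = stimWindowS,
      stimRateHz = stimRateHz,
      postStimDecayTauMs = postStimDecayTauMs,
      vhpcKernel = vhpcKernel,
      vhpcNmdaKernel = vhpcNmdaKernel,
      vhpcNoiseRateHz = vhpcNoiseRateHz,
      neuronNoise = neuronNoise,
      pyrConnectionProb = pyrConnectionProb,
      smoothingSigmaMs = smoothingSigmaMs)
}

#' Construct a spectral photometry timeseries
#'
#' @param counts wavelength x frame matrix of photon counts.
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param rateHz acquisition rate (Hz), typically 20 or 40.
#' @param t0 session-relative start time of the first frame (s).
#' @return a [SpectralTimeseries-class] object.
#' @export
spectralTimeseries <- function(counts, wavelengths, rateHz, t0 = 0) {
  stopifnot(nrow(counts) == length(wavelengths))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(wavelength_nm = wavelengths),
    metadata = list(rate_hz = rateHz, t0 = t0))
  new("SpectralTimeseries", se)
}

#' Construct transient-detection parameters
#'
#' Defaults follow the published analysis of spontaneous calcium events:
#' magnitude threshold 2.91 x MAD (the two-sided 95% Gaussian quantile over
#' the Gaussian quartile deviation, so MAD is used unscaled), admissible
#' half-magnitude widths 0.5-10 s, minimum peak separation 1 s, and a 1.6-s
#' feature window.
#'
#' @param madMultiplier,minWidthS,maxWidthS,minSeparationS,featureWindowS see
#'   [TransientParams-class].
#' @return a [TransientParams-class] object.
#' @export
transientParams <- function(madMultiplier = 2.91, minWidthS = 0.5,
                            maxWidthS = 10, minSeparationS = 1,
                            featureWindowS = 1.6) {
  new("TransientParams", madMultiplier = madMultiplier, minWidthS = minWidthS,
      maxWidthS = maxWidthS, minSeparationS = minSeparationS,
      featureWindowS = featureWindowS)
}

#' Construct a trial-level functional dataset
#'
#' @param Y trials x timepoints signal matrix.
#' @param covariates per-trial covariate data.frame (see
#'   [FunctionalDataset-class] for the required codings).
#' @param mouse cluster (mouse) id per trial.
#' @param time timepoint grid (s).
#' @return a [FunctionalDataset-class] object.
#' @export
functionalDataset <- function(Y, covariates, mouse, time) {
  new("FunctionalDataset", Y = as.matrix(Y),
      covariates = as.data.frame(covariates),
      mouse = factor(mouse), time = time)
}

#' Construct synthetic-data generator parameters
#'
#' The defaults define the study conditions every synthetic dataset emulates:
#' 6 mice per group with 100 task trials each (10 per training day), 20-Hz
#' spectral acquisition, GCaMP-dominant baseline counts with a flat
#' background, 20% linear bleaching per session, a slow (10-s) shared
#' multiplicative motion artifact of 5% amplitude, GCaMP6f-like transient
#' kinetics (rise 50 ms, decay 500 ms) with spontaneous events modeled as
#' brief bursts at 0.1 Hz, unit-SD smooth residual noise, 0.3-SD per-mouse
#' random intercepts, no injected distal-delay effects, and VIP-like negative
#' velocity coupling with calcium leading by 0.5 s.
#'
#' @param ... named overrides of any [GeneratorParams-class] slot.
#' @return a [GeneratorParams-class] object.
#' @examples
#' p <- generatorParams(distalEffects = c(outcome = 0, training = 0,
#'                                        group = 0, training_x_group = -0.5))
#' @export
generatorParams <- function(...) {
  defaults <- list(
    nMicePerGroup = 6L,
    trialsPerMouse = 100L,
    rateHz = 20,
    baselineCounts = c(gcamp = 600, tdtomato = 400),
    backgroundCounts = 2,
    bleachFrac = 0.2,
    motionAmplitude = 0.05,
    motionTauS = 10,
    transientRiseS = 0.05,
    transientDecayS = 0.5,
    spontRateHz = 0.1,
    spontAmpMeanLog = log(3),
    spontAmpSdLog = 0.3,
    burstMeanExtra = 4,
    minEventSeparationS = 2,
    noiseSd = 1,
    noiseSmoothS = 0.2,
    randomInterceptSd = 0.3,
    distalEffects = c(outcome = 0, training = 0, group = 0,
                      training_x_group = 0),
    accuracyCoupling = 0,
    velocityGain = -0.5,
    velocityLagS = 0.5,
    delayS = 10
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown generator parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  defaults$nMicePerGroup <- as.integer(defaults$nMicePerGroup)
  defaults$trialsPerMouse <- as.integer(defaults$trialsPerMouse)
  do.call(new, c(list("GeneratorParams"), defaults))
}

configHash <- function(config) rlang::hash(config)
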