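#' Sample a random pyramidal-pyramidal connectivity matrix
#'
#' Each ordered pair of distinct pyramidal cells is connected independently
#' with probability `p`; self-connections are excluded (zero diagonal).
#' Entry `[i, j] = 1` means cell `j` projects onto cell `i`.
#'
#' @param n number of pyramidal cells.
#' @param p connection probability in \[0, 1\].
#' @param seed integer seed for reproducibility.
#' @return binary `n x n` matrix with zero diagonal.
#' @examples
#' M <- buildPyrConnectivity(20, 0.2, seed = 1)
#' all(diag(M) == 0)
#' @export
buildPyrConnectivity <- function(n, p, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.finite(p) || p < 0 || p > 1) stop("connection probability must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restoreSeed(old))
    set.seed(seed)
  }
  M <- matrix(rbinom(n * n, 1L, p), n, n)
  diag(M) <- 0L
  M
}

restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

withSeed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(restoreSeed(old))
  set.seed(seed)
  expr
}

#' Time-varying vHPC input event rate
#'
#' Zero before stimulation onset, the stimulation rate inside the window, and
#' an exponential decay (time constant `postStimDecayTauMs`) afterwards.
#'
#' @param config a [NetworkConfig-class].
#' @param timeS vector of times (s).
#' @return event rate in Hz at each time.
#' @export
vhpcRate <- function(config, timeS) {
  on <- config@stimWindowS[1]; off <- config@stimWindowS[2]
  r <- numeric(length(timeS))
  during <- timeS > on & timeS <= off
  after <- timeS > off
  r[during] <- config@stimRateHz
  r[after] <- config@stimRateHz *
    exp(-(timeS[after] - off) * 1000 / config@postStimDecayTauMs)
  r
}

#' Sample a vHPC stimulation event raster
#'
#' Draws, for every integration step, at most one vHPC input event with
#' probability `rate(t) * dt`, where the rate is 0 before stimulation onset,
#' the stimulation rate (default 100 Hz, so an expected 100 events in the
#' 1-s window) during stimulation, and decays exponentially with tau 1000 ms
#' afterwards.
#'
#' @param config a [NetworkConfig-class].
#' @param seed integer seed.
#' @return integer 0/1 vector over the step grid (times `(1:n) * dt`).
#' @export
sampleVhpcRaster <- function(config, seed = NULL) {
  tm <- stepTimes(config)
  p <- vhpcRate(config, tm) * config@dtMs / 1000
  if (any(p > 1))
    stop("event probability rate*dt exceeds 1: the raster is undersampled")
  if (!is.null(seed)) withSeed(seed, rbinom(length(p), 1L, p))
  else rbinom(length(p), 1L, p)
}

stepTimes <- function(config) {
  n <- nSteps(config)
  (1:n) * config@dtMs / 1000
}

nSteps <- function(config) as.integer(round(config@durationS * 1000 / config@dtMs))

#' Filter an event raster with a truncated causal exponential kernel
#'
#' Convolves a 0/1 raster (or any signal) with
#' `k[j] = amplitude * exp(-j * dt / tau)` for `j = 0, ..., lengthSteps - 1`
#' and zero beyond, so each event of amplitude 1 decays over `lengthSteps`
#' steps with time constant `tau`.
#'
#' @param raster numeric vector or matrix (columns filtered independently).
#' @param amplitude event amplitude.
#' @param tauMs decay time constant (ms).
#' @param lengthSteps kernel support length in steps.
#' @param dtMs step size (ms).
#' @return filtered signal, same shape as `raster`.
#' @examples
#' x <- numeric(200); x[10] <- 1
#' y <- expKernelFilter(x, 1, tauMs = 8, lengthSteps = 40, dtMs = 0.1)
#' y[10 + 80] # exp(-1) if the kernel were longer; here 0 (beyond 40 steps)
#' @export
expKernelFilter <- function(raster, amplitude, tauMs, lengthSteps, dtMs) {
  if (tauMs <= 0 || dtMs <= 0) stop("tau and dt must be positive")
  if (lengthSteps < 1) stop("lengthSteps must be >= 1")
  # truncated exponential convolution in O(n) via its exact recursion:
  # y[t] = d*y[t-1] + x[t] - d^L * x[t-L]
  d <- exp(-dtMs / tauMs)
  x <- if (is.matrix(raster)) raster else matrix(raster, ncol = 1)
  storage.mode(x) <- "double"
  y <- exp_filter(x, d, as.integer(lengthSteps), amplitude)
  if (is.matrix(raster)) { dimnames(y) <- dimnames(raster); y }
  else as.numeric(y)
}

#' Build all external drive signals for one run
#'
#' Samples the vHPC stimulation raster, the background vHPC noise raster, and
#' one noise raster per neuron, and filters each with its exponential kernel:
#' the stimulation raster through both the AMPA-like (tau 8 ms, 40 steps) and
#' NMDA-like (tau 80 ms, 400 steps) kernels, the noise rasters through the
#' AMPA-like kernel, with per-class amplitudes for neuron noise.
#'
#' @param config a [NetworkConfig-class].
#' @param seed integer seed.
#' @return list with `ampa`, `nmda`, `noise` (step-grid vectors),
#'   `neuron` (neurons x steps matrix), and `raster` (the 0/1 stimulation raster).
#' @export
buildExternalDrive <- function(config, seed = NULL) {
  force(config)
  build <- function() {
    n <- nSteps(config)
    raster <- {
      tm <- stepTimes(config)
      p <- vhpcRate(config, tm) * config@dtMs / 1000
      if (any(p > 1)) stop("event probability rate*dt exceeds 1")
      rbinom(n, 1L, p)
    }
    noiseP <- config@vhpcNoiseRateHz * config@dtMs / 1000
    noiseRaster <- rbinom(n, 1L, noiseP)
    nn <- config@neuronNoise
    nNeurons <- sum(config@nCells)
    nnP <- nn$rate_hz * config@dtMs / 1000
    nnRaster <- matrix(rbinom(n * nNeurons, 1L, nnP), nrow = n, ncol = nNeurons)
    amp <- rep(nn$amplitude[CELL_CLASSES], times = config@nCells[CELL_CLASSES])
    filt <- function(x, tau, len, a = 1)
      expKernelFilter(x, a, tau, len, config@dtMs)
    neuron <- filt(nnRaster, nn$tau_ms, nn$length_steps)
    neuron <- sweep(neuron, 2, amp, "*")
    list(
      ampa = filt(raster, config@vhpcKernel["tau_ms"],
                  config@vhpcKernel["length_steps"]),
      nmda = filt(raster, config@vhpcNmdaKernel["tau_ms"],
                  config@vhpcNmdaKernel["length_steps"]),
      noise = filt(noiseRaster, nn$tau_ms, nn$length_steps),
      neuron = t(neuron),
      raster = raster)
  }
  if (!is.null(seed)) withSeed(seed, build()) else build()
}

newNetworkState <- function(config) {
  nNeurons <- sum(config@nCells)
  list(
    v = numeric(nNeurons),
    out = c(VIP = 0, SST = 0, PV = 0, PYR_AMPA = 0, PYR_NMDA = 0),
    out2a = numeric(config@nCells["PYR"]),
    out2n = numeric(config@nCells["PYR"]),
    refract = logical(nNeurons))
}

classIndex <- function(config) {
  rep(CELL_CLASSES, times = config@nCells[CELL_CLASSES])
}

#' Advance the network by one integration step (reference implementation)
#'
#' The naive per-step update used as the oracle for the compiled engine.
#' For every neuron not in its post-spike reset step, the membrane voltage is
#' decayed by `exp(-dt/tau_m)` and incremented by `dt` times the summed
#' input: minus the weighted VIP, SST and PV class outputs; plus the weighted
#' pyramidal drive (class-level AMPA + 0.3 NMDA outputs for interneurons, or
#' the connectivity-masked per-cell outputs for pyramidal cells); plus the
#' weighted vHPC drive (AMPA + 0.3 NMDA + shared noise); plus the neuron's
#' own noise. Neurons at or above threshold fire; a neuron that fired on the
#' previous step has its voltage forced to the reset value this step and
#' integrates normally again on the next. Class outputs then decay by
#' `exp(-dt/tau_syn)` and increment by the proportion of the class that
#' fired; per-pyramidal-cell outputs increment by 1 when that cell fired.
#'
#' @param state state list (zero-initialized by the run functions): voltages `v`, class
#'   outputs `out`, per-pyramidal-cell outputs `out2a`/`out2n`, and the
#'   `refract` flags of neurons that fired on the previous step.
#' @param drive list with scalars `ampa`, `nmda`, `noise` and per-neuron
#'   vector `neuron`, all evaluated at the *previous* step.
#' @param config a [NetworkConfig-class].
#' @param pyrConnectivity binary matrix from [buildPyrConnectivity()].
#' @return list with the updated `state` and the logical vector `spiked`.
#' @export
stepNetwork <- function(state, drive, config, pyrConnectivity) {
  W <- config@weights
  dt <- config@dtMs
  vdecay <- exp(-dt / config@tauMembraneMs)
  ns <- config@nmdaScale
  cls <- classIndex(config)
  nn <- config@nCells
  pyrIdx <- which(cls == "PYR")

  out <- state$out
  inputs <- numeric(length(state$v))
  for (x in CELL_CLASSES) {
    idx <- which(cls == x)
    inh <- W["VIP", x] * out["VIP"] + W["SST", x] * out["SST"] +
      W["PV", x] * out["PV"]
    vh <- W["vHPC", x] * (drive$ampa + ns * drive$nmda + drive$noise)
    if (x == "PYR") {
      rec <- W["PYR", "PYR"] *
        as.numeric(pyrConnectivity %*% (state$out2a + ns * state$out2n))
      inputs[idx] <- -inh + rec + vh + drive$neuron[idx]
    } else {
      exc <- W["PYR", x] * (out["PYR_AMPA"] + ns * out["PYR_NMDA"])
      inputs[idx] <- -inh + exc + vh + drive$neuron[idx]
    }
  }
  v <- state$v * vdecay + dt * inputs
  v[state$refract] <- config@resetValue
  if (any(!is.finite(v)))
    stop("non-finite membrane voltage encountered")
  spiked <- v >= config@spikeThreshold

  sdec <- exp(-dt / config@tauSynMs)
  newOut <- out
  for (x in c("VIP", "SST", "PV")) {
    idx <- which(cls == x)
    newOut[x] <- out[x] * sdec[x] + sum(spiked[idx]) / nn[x]
  }
  pSpk <- spiked[pyrIdx]
  newOut["PYR_AMPA"] <- out["PYR_AMPA"] * sdec["PYR_AMPA"] + sum(pSpk) / nn["PYR"]
  newOut["PYR_NMDA"] <- out["PYR_NMDA"] * sdec["PYR_NMDA"] + sum(pSpk) / nn["PYR"]
  out2a <- state$out2a * sdec["PYR_AMPA"] + as.numeric(pSpk)
  out2n <- state$out2n * sdec["PYR_NMDA"] + as.numeric(pSpk)

  list(state = list(v = v, out = newOut, out2a = out2a, out2n = out2n,
                    refract = spiked),
       spiked = spiked)
}

#' Run the network with the pure-R per-step reference engine
#'
#' Iterates [stepNetwork()] over the whole step grid. Intended as an
#' independent oracle for [runSimulation()]'s compiled engine; it is orders
#' of magnitude slower and should only be used on short grids.
#'
#' @param config a [NetworkConfig-class].
#' @param drive drive list from [buildExternalDrive()].
#' @param pyrConnectivity binary connectivity matrix.
#' @param recordV if `TRUE`, also return the neurons x steps voltage matrix.
#' @return list with `spikes` (neurons x steps logical), per-class
#'   `spikeCounts` (classes x steps), and optionally `v`.
#' @export
runSimulationReference <- function(config, drive, pyrConnectivity,
                                   recordV = FALSE) {
  n <- nSteps(config)
  cls <- classIndex(config)
  state <- newNetworkState(config)
  spikes <- matrix(FALSE, length(state$v), n)
  vrec <- if (recordV) matrix(0, length(state$v), n) else NULL
  for (t in seq_len(n)) {
    dAt <- if (t == 1L)
      list(ampa = 0, nmda = 0, noise = 0, neuron = numeric(length(state$v)))
    else
      list(ampa = drive$ampa[t - 1], nmda = drive$nmda[t - 1],
           noise = drive$noise[t - 1], neuron = drive$neuron[, t - 1])
    res <- stepNetwork(state, dAt, config, pyrConnectivity)
    state <- res$state
    spikes[, t] <- res$spiked
    if (recordV) vrec[, t] <- state$v
  }
  counts <- countsByClass(spikes, cls)
  out <- list(spikes = spikes, spikeCounts = counts)
  if (recordV) out$v <- vrec
  out
}

countsByClass <- function(spikes, cls) {
  counts <- matrix(0L, 4L, ncol(spikes), dimnames = list(CELL_CLASSES, NULL))
  for (x in CELL_CLASSES)
    counts[x, ] <- as.integer(colSums(spikes[cls == x, , drop = FALSE]))
  counts
}

#' Gaussian-smooth spike-count traces into photometry-like activity
#'
#' Convolves each row with a symmetric Gaussian kernel (sigma in ms,
#' truncated at +/-4 sigma, unit mass) via FFT; near the record edges the
#' kernel is renormalized over its in-range support so the smoother remains
#' an average.
#'
#' @param counts classes x steps matrix (or a vector).
#' @param sigmaMs kernel sigma (ms).
#' @param dtMs step size (ms).
#' @return smoothed matrix (or vector) of the same shape.
#' @export
smoothActivity <- function(counts, sigmaMs, dtMs) {
  vec <- is.null(dim(counts))
  if (vec) counts <- matrix(counts, nrow = 1)
  sigma <- sigmaMs / dtMs
  half <- ceiling(4 * sigma)
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- ncol(counts)
  m <- n + 2L * half
  N <- nextn(m)
  K <- fft(c(k, numeric(N - length(k))))
  norm <- Re(fft(fft(c(rep(1, n), numeric(N - n))) * K, inverse = TRUE)) / N
  norm <- norm[(half + 1):(half + n)]
  sm <- t(apply(counts, 1, function(x) {
    y <- Re(fft(fft(c(x, numeric(N - n))) * K, inverse = TRUE)) / N
    y[(half + 1):(half + n)] / norm
  }))
  if (vec) as.numeric(sm) else {
    dimnames(sm) <- dimnames(counts)
    sm
  }
}

#' Run one seeded simulation of the microcircuit
#'
#' Samples all stochastic inputs (stimulation raster, vHPC noise, per-neuron
#' noise, pyramidal connectivity) from `seed`, integrates the network with
#' the compiled engine from zero initial voltages and outputs, and records
#' the per-class spike counts at every step plus their Gaussian-smoothed
#' (sigma = `smoothingSigmaMs`) photometry-like activity traces.
#'
#' @param config a [NetworkConfig-class].
#' @param seed integer seed; identical (config, seed) pairs give identical output.
#' @return a [SimulationOutput-class].
#' @examples
#' cfg <- networkConfig(durationS = 0.5, stimWindowS = c(0.2, 0.3))
#' sim <- runSimulation(cfg, seed = 1)
#' sim
#' @export
runSimulation <- function(config, seed) {
  validObject(config)
  seed <- as.integer(seed)
  M <- withSeed(seed, {
    M <- buildPyrConnectivity(config@nCells["PYR"], config@pyrConnectionProb)
    M
  })
  drive <- buildExternalDrive(config, seed = seed + 1L)
  eng <- runEngine(config, drive, M)
  act <- smoothActivity(eng$spikeCounts, config@smoothingSigmaMs, config@dtMs)
  new("SimulationOutput",
      spikeCounts = eng$spikeCounts,
      activity = act,
      time = stepTimes(config),
      seed = seed,
      configHash = configHash(config))
}

#' Run the compiled integration engine on precomputed drives
#'
#' Thin wrapper around the Rcpp core implementing exactly the update of
#' [stepNetwork()]. Exposed so the engine can be compared against the
#' per-step reference on identical inputs.
#'
#' @inheritParams runSimulationReference
#' @return list with `spikeCounts` (classes x steps) and, if `recordV`,
#'   the voltage matrix `v`.
#' @export
runEngine <- function(config, drive, pyrConnectivity, recordV = FALSE) {
  nn <- config@nCells
  sdec <- exp(-config@dtMs / config@tauSynMs)
  res <- engine_run(
    drive$ampa, drive$nmda, drive$noise, drive$neuron,
    config@weights, pyrConnectivity,
    as.integer(nn[CELL_CLASSES]),
    exp(-config@dtMs / config@tauMembraneMs),
    sdec, config@nmdaScale, config@spikeThreshold, config@resetValue,
    config@dtMs, recordV)
  counts <- res$spikeCounts
  dimnames(counts) <- list(CELL_CLASSES, NULL)
  out <- list(spikeCounts = counts)
  if (recordV) out$v <- res$v
  out
}

#' Average smoothed activity over repeated runs
#'
#' One "simulation" of the model is the element-wise mean of the smoothed
#' activity traces over `nRuns` (default 5) independent runs.
#'
#' @param config a [NetworkConfig-class].
#' @param nRuns number of runs to average.
#' @param seed master seed from which per-run seeds are drawn, or `seeds`, an
#'   explicit integer vector of length `nRuns`.
#' @param seeds optional explicit per-run seeds (overrides `seed`).
#' @return an [ActivityTrace-class].
#' @export
simulateCondition <- function(config, nRuns = 5L, seed = NULL, seeds = NULL) {
  if (is.null(seeds)) {
    if (is.null(seed)) stop("provide seed or seeds")
    seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, nRuns))
  }
  if (length(seeds) != nRuns) stop("need one seed per run")
  acc <- NULL
  tm <- NULL
  for (s in seeds) {
    sim <- runSimulation(config, s)
    if (is.null(acc)) { acc <- sim@activity; tm <- sim@time }
    else {
      if (ncol(sim@activity) != ncol(acc))
        stop("internal error: mismatched trace lengths across runs")
      acc <- acc + sim@activity
    }
  }
  new("ActivityTrace", activity = acc / nRuns, time = tm,
      nRuns = as.integer(nRuns), seeds = as.integer(seeds),
      configHash = configHash(config))
}

#' Baseline-subtracted evoked peak of an activity trace
#'
#' Subtracts the mean over the baseline window (default 0.1-2 s) and returns
#' the maximum over the response window (default stimulation onset to the end
#' of the simulation, 2-10 s).
#'
#' @param trace numeric activity trace.
#' @param time time grid (s) of the trace.
#' @param baselineWindow,responseWindow closed intervals (s).
#' @return scalar evoked peak.
#' @export
evokedPeak <- function(trace, time, baselineWindow = c(0.1, 2),
                       responseWindow = c(2, 10)) {
  bi <- time >= baselineWindow[1] & time <= baselineWindow[2]
  ri <- time >= responseWindow[1] & time <= responseWindow[2]
  if (!any(bi) || !any(ri)) stop("empty baseline or response window")
  max(trace[ri] - mean(trace[bi]))
}
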