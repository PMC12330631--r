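#' Default wavelength grid of the synthetic spectrometer
#'
#' A 400-700 nm grid at 2-nm spacing: wide enough to contain both emission
#' bands (500-541 and 577-618 nm) with margins, small enough to keep
#' synthetic sessions light.
#'
#' @return numeric wavelength grid (nm).
#' @export
defaultWavelengthGrid <- function() seq(400, 700, by = 2)

#' Gaussian-profile reference emission spectra
#'
#' Builds unit-Euclidean-norm Gaussian emission profiles for a GCaMP-like
#' (peak 513 nm) and a tdTomato-like (peak 581 nm) fluorophore, so that the
#' bulk of each profile's mass falls inside its conventional summation band
#' (500-541 and 577-618 nm respectively).
#'
#' @param gridNm wavelength grid (nm).
#' @param peaksNm emission peaks (nm) of the two fluorophores.
#' @param widthsNm Gaussian SDs (nm).
#' @return a [ReferenceSpectra-class] with columns `gcamp`, `tdtomato`.
#' @export
makeReferenceSpectra <- function(gridNm = defaultWavelengthGrid(),
                                 peaksNm = c(513, 581),
                                 widthsNm = c(12, 12)) {
  if (any(peaksNm < min(gridNm)) || any(peaksNm > max(gridNm)))
    stop("emission peaks must lie inside the wavelength grid")
  S <- vapply(seq_along(peaksNm), function(k) {
    s <- exp(-((gridNm - peaksNm[k])^2) / (2 * widthsNm[k]^2))
    s / sqrt(sum(s^2))
  }, numeric(length(gridNm)))
  colnames(S) <- c("gcamp", "tdtomato")[seq_along(peaksNm)]
  new("ReferenceSpectra", wavelengths = gridNm, spectra = S)
}

# difference-of-exponentials calcium transient, peak-normalized to 1
transientKernel <- function(riseS, decayS, rateHz) {
  tt <- seq(0, 6 * decayS, by = 1 / rateHz)
  k <- exp(-tt / decayS) - exp(-tt / riseS)
  k / max(k)
}

# smooth unit-SD Gaussian noise
smoothNoise <- function(n, smoothS, rateHz, sdTarget = 1) {
  w <- rnorm(n)
  if (smoothS > 0) {
    sm <- smoothActivity(w, smoothS * 1000, 1000 / rateHz)
    sm / sd(sm) * sdTarget
  } else w * sdTarget
}

# hard-core event times: exponential gaps with a minimum separation
sampleEventTimes <- function(durationS, rateHz, minSepS) {
  if (rateHz <= 0) return(numeric())
  times <- numeric()
  t <- rexp(1, rateHz)
  while (t < durationS) {
    times <- c(times, t)
    t <- t + minSepS + rexp(1, rateHz)
  }
  times
}

#' Generate a spontaneous calcium activity trace with ground truth
#'
#' The generator's model of baseline population calcium activity: white
#' Gaussian noise (frame-to-frame variability of photometry signals is
#' photon shot noise, which is uncorrelated across frames) plus spontaneous
#' calcium events at a hard-core Poisson rate. Each event is a brief burst
#' of `3 + Poisson(burstMeanExtra)` transient kernels stacked 100 ms apart
#' - population events are compound, which is what places their
#' half-magnitude widths (roughly 0.6-1.5 s under the defaults) inside the
#' 0.5-10-s band the event analysis treats as admissible - with a lognormal
#' per-spike amplitude shared within the burst.
#'
#' @param params a [GeneratorParams-class].
#' @param durationS trace duration (s).
#' @param rateHz sampling rate.
#' @param seed integer seed (optional; inherits the RNG state when `NULL`).
#' @return list with `trace` (numeric), `events` (data.frame: `time_s` of
#'   burst onset, `peak_time_s`, `amplitude` = the event's peak contribution)
#'   and `rateHz`.
#' @export
makeSpontaneousTrace <- function(params, durationS = 600, rateHz = 10,
                                 seed = NULL) {
  build <- function() {
    n <- round(durationS * rateHz)
    kern <- transientKernel(params@transientRiseS, params@transientDecayS,
                            rateHz)
    trace <- rnorm(n, 0, params@noiseSd)
    onsets <- sampleEventTimes(durationS, params@spontRateHz,
                               params@minEventSeparationS)
    ev <- list()
    for (t0 in onsets) {
      nSpk <- 3L + rpois(1, params@burstMeanExtra)
      amp <- rlnorm(1, params@spontAmpMeanLog, params@spontAmpSdLog)
      contrib <- numeric(n)
      for (s in seq_len(nSpk)) {
        i0 <- round((t0 + (s - 1) * 0.1) * rateHz) + 1
        if (i0 > n) break
        i1 <- min(n, i0 + length(kern) - 1L)
        contrib[i0:i1] <- contrib[i0:i1] + amp * kern[seq_len(i1 - i0 + 1L)]
      }
      trace <- trace + contrib
      ev[[length(ev) + 1L]] <-
        data.frame(time_s = t0,
                   peak_time_s = (which.max(contrib) - 1) / rateHz,
                   amplitude = max(contrib))
    }
    events <- if (length(ev)) do.call(rbind, ev)
      else data.frame(time_s = numeric(), peak_time_s = numeric(),
                      amplitude = numeric())
    list(trace = trace, events = events, rateHz = rateHz)
  }
  if (!is.null(seed)) withSeed(seed, build()) else build()
}

#' Mix fluorophore coefficient traces into a photon-count spectrum
#'
#' The forward model inverted by [linearUnmix()]: each frame's expected
#' spectrum is `coef_gcamp * ref_gcamp + coef_tdtomato * ref_tdtomato +
#' coef_background * u`, with `u` the constant unit-norm background profile.
#' With `poisson = TRUE` the counts are Poisson-sampled (non-negative
#' expected counts required).
#'
#' @param coefs components x frames matrix with rows `gcamp`, `tdtomato` and
#'   optionally `background`.
#' @param refs a [ReferenceSpectra-class].
#' @param rateHz acquisition rate recorded in the output.
#' @param poisson apply Poisson photon noise.
#' @return a [SpectralTimeseries-class].
#' @export
mixSpectra <- function(coefs, refs, rateHz, poisson = FALSE) {
  R <- refs@spectra
  if ("background" %in% rownames(coefs)) {
    bg <- rep(1 / sqrt(nrow(R)), nrow(R))
    R <- cbind(R, background = bg)
  }
  mu <- R %*% coefs[colnames(R), , drop = FALSE]
  if (any(mu < 0)) mu[mu < 0] <- 0
  counts <- if (poisson)
    matrix(rpois(length(mu), mu), nrow(mu), ncol(mu)) else mu
  spectralTimeseries(counts, refs@wavelengths, rateHz)
}

# per-trial distal-delay shift implied by covariates and injected effects
distalShift <- function(effects, training, outcome, group) {
  effects[["outcome"]] * outcome + effects[["training"]] * training +
    effects[["group"]] * group +
    effects[["training_x_group"]] * training * group
}

# trial event schedule for one session; delay epoch is exactly delayS
scheduleTrials <- function(nTrials, delayS, itiS = 20) {
  sampleDur <- runif(nTrials, 3, 6)
  choiceDur <- runif(nTrials, 2, 5)
  sampleStart <- numeric(nTrials)
  t <- 5
  trials <- vector("list", nTrials)
  for (k in seq_len(nTrials)) {
    ss <- t
    se <- ss + sampleDur[k]
    cs <- se + delayS
    ce <- cs + choiceDur[k]
    trials[[k]] <- data.frame(trial_index = k, sample_start = ss,
                              sample_end = se, delay_start = se,
                              choice_start = cs, choice_end = ce)
    t <- ce + itiS
  }
  do.call(rbind, trials)
}

#' Simulate one spatial working-memory photometry session
#'
#' Generates, for one mouse, a complete synthetic task session: a trial
#' table with 10-s delay epochs, a spectral photometry record, a 10-Hz
#' velocity trace, and the ground truth behind all of them. The calcium
#' activity is spontaneous baseline activity ([makeSpontaneousTrace()]) plus
#' a per-trial distal-delay shift composed of the injected
#' group/outcome/training effects and the mouse's random intercept. Both
#' fluorophores are mixed through the reference spectra, multiplied by a
#' shared slow motion artifact and a linear bleach, and Poisson-sampled.
#' Velocity is linearly coupled to the calcium truth with the configured
#' gain and lag.
#'
#' @param params a [GeneratorParams-class].
#' @param mouseId mouse label.
#' @param seed integer seed.
#' @param nTrials trials in the session.
#' @param group 0/1 group label (NS-like vs manipulated).
#' @param trainingFraction training fractions of the session's trials
#'   (recycled; defaults to equally spaced over \[0, 1\]).
#' @param refs reference spectra used for mixing.
#' @return list with `spectra` ([SpectralTimeseries-class]), `trials`
#'   (trial-table data.frame with mouse id, covariates and event times),
#'   `velocity` (data.frame `time_s`, `velocity`), and `truth` (list:
#'   activity trace, coefficient traces, events, per-trial distal shifts,
#'   random intercept, velocity lag).
#' @export
simulateSwmSession <- function(params, mouseId = "m01", seed = 1L,
                               nTrials = 20L, group = 0L,
                               trainingFraction = NULL,
                               refs = makeReferenceSpectra()) {
  withSeed(seed, {
    rateHz <- params@rateHz
    trials <- scheduleTrials(nTrials, params@delayS)
    durationS <- max(trials$choice_end) + 5
    n <- round(durationS * rateHz)
    tm <- (seq_len(n) - 1) / rateHz

    if (is.null(trainingFraction))
      trainingFraction <- if (nTrials == 1L) 0 else
        (seq_len(nTrials) - 1) / (nTrials - 1)
    gamma <- rnorm(1, 0, params@randomInterceptSd)
    eff <- params@distalEffects

    preOutcome <- distalShift(eff, trainingFraction, 0, group) + gamma
    pIncorrect <- plogis(qlogis(0.3) - 1.0 * trainingFraction +
                           params@accuracyCoupling * preOutcome)
    outcome <- rbinom(nTrials, 1L, pIncorrect)
    delta <- distalShift(eff, trainingFraction, outcome, group) + gamma

    base <- makeSpontaneousTrace(params, durationS, rateHz)
    activity <- base$trace
    for (k in seq_len(nTrials)) {
      cs <- trials$choice_start[k]
      idx <- which(tm >= cs - 2 & tm < cs)
      activity[idx] <- activity[idx] + delta[k]
    }

    cv <- 0.1
    bleach <- 1 - params@bleachFrac * (seq_len(n) - 1) / max(n - 1, 1)
    motion <- 1 + params@motionAmplitude *
      smoothNoise(n, params@motionTauS, rateHz)
    motion[motion < 0.1] <- 0.1
    cg <- params@baselineCounts[["gcamp"]] * pmax(1 + cv * activity, 0.05) *
      bleach * motion
    ct <- params@baselineCounts[["tdtomato"]] * bleach * motion
    coefs <- rbind(gcamp = cg, tdtomato = ct,
                   background = rep(params@backgroundCounts, n))
    spectra <- mixSpectra(coefs, refs, rateHz, poisson = TRUE)

    lagSamp <- round(params@velocityLagS * 10)
    a10 <- downsampleMean(activity, rateHz, 10)
    n10 <- length(a10)
    aLag <- c(rep(a10[1], lagSamp), a10)[seq_len(n10)]
    velocity <- pmax(0, 3 + params@velocityGain * aLag + rnorm(n10, 0, 0.3))

    trials$mouse_id <- mouseId
    trials$training_fraction <- trainingFraction
    trials$outcome <- outcome
    trials$stimulation <- group
    trials$genotype <- group

    list(spectra = spectra,
         trials = trials,
         velocity = data.frame(time_s = (seq_len(n10) - 1) / 10,
                               velocity = velocity),
         truth = list(activity = activity, time_s = tm,
                      coefficients = coefs, events = base$events,
                      distal_shift = delta, random_intercept = gamma,
                      velocity_lag_s = params@velocityLagS,
                      velocity_gain = params@velocityGain))
  })
}

#' Simulate one optogenetic stimulation-photometry day
#'
#' A 40-Hz session comprising a 10-min baseline period of spontaneous
#' activity followed by 30-s stimulation trials whose evoked calcium
#' transient (at the 10-s mark of each trial) is scaled by the day's
#' plasticity multiplier - a depressing profile emulates VIP-like responses
#' across days, a potentiating one SST-like responses.
#'
#' @param params a [GeneratorParams-class] (`rateHz` is overridden to 40).
#' @param dayIndex which day of the profile to simulate.
#' @param plasticityProfile numeric vector of per-day evoked-amplitude
#'   multipliers.
#' @param seed integer seed.
#' @param nTrials number of 30-s stimulation trials.
#' @param evokedAmplitude evoked transient amplitude (activity units) at
#'   multiplier 1.
#' @param baselineS baseline duration before the first trial (s).
#' @param refs reference spectra used for mixing.
#' @return list with `spectra` ([SpectralTimeseries-class]), `trialStarts`
#'   (s), and `truth` (activity trace, coefficient traces, events, evoked
#'   amplitude used).
#' @export
simulateStimDay <- function(params, dayIndex, plasticityProfile, seed = 1L,
                            nTrials = 10L, evokedAmplitude = 5,
                            baselineS = 600,
                            refs = makeReferenceSpectra()) {
  if (dayIndex < 1 || dayIndex > length(plasticityProfile))
    stop("dayIndex outside the plasticity profile")
  withSeed(seed, {
    rateHz <- 40
    trialStarts <- baselineS + (seq_len(nTrials) - 1) * 30
    durationS <- baselineS + nTrials * 30
    n <- round(durationS * rateHz)
    base <- makeSpontaneousTrace(params, durationS, rateHz)
    activity <- base$trace
    amp <- evokedAmplitude * plasticityProfile[dayIndex]
    kern <- transientKernel(params@transientRiseS, params@transientDecayS,
                            rateHz)
    for (ts in trialStarts) {
      i0 <- round((ts + 10) * rateHz) + 1
      i1 <- min(n, i0 + length(kern) - 1L)
      activity[i0:i1] <- activity[i0:i1] + amp * kern[seq_len(i1 - i0 + 1L)]
    }
    cv <- 0.1
    bleach <- 1 - params@bleachFrac * (seq_len(n) - 1) / max(n - 1, 1)
    cg <- params@baselineCounts[["gcamp"]] * pmax(1 + cv * activity, 0.05) *
      bleach
    ct <- params@baselineCounts[["tdtomato"]] * bleach
    coefs <- rbind(gcamp = cg, tdtomato = ct,
                   background = rep(params@backgroundCounts, n))
    spectra <- mixSpectra(coefs, refs, rateHz, poisson = TRUE)
    list(spectra = spectra, trialStarts = trialStarts,
         truth = list(activity = activity, coefficients = coefs,
                      events = base$events, evoked_amplitude = amp))
  })
}

#' Simulate a full multi-mouse cohort for functional regression and behavior
#'
#' Generates trial-level z-scale calcium signals on a 10-s peri-choice
#' window (10 Hz, t = -8 ... +1.9 s relative to Choice Start) for two groups
#' of mice, together with the matching training record. Each trial's signal
#' is a smooth choice-related template, plus the mouse's random intercept,
#' plus the injected distal-delay shift (constant over the final 2 s of the
#' delay), plus smooth unit-SD noise. Outcomes are Bernoulli with a logistic
#' link whose linear predictor improves with training and, when
#' `accuracyCoupling > 0`, worsens with the trial's pre-outcome distal-delay
#' activity - making the distal-score-to-accuracy correlation controllable.
#'
#' @param params a [GeneratorParams-class].
#' @param seed integer seed.
#' @return list with `dataset` ([FunctionalDataset-class]), `record`
#'   (training-record data.frame, 10 trials/day), and `truth` (per-mouse
#'   random intercepts, per-trial distal shifts, injected effects, the
#'   distal-window index mask).
#' @export
simulateCohort <- function(params, seed = 1L) {
  withSeed(seed, {
    timeGrid <- seq(-8, 1.9, by = 0.1)
    nT <- length(timeGrid)
    distalMask <- timeGrid >= -2 & timeGrid < 0
    template <- 0.3 * exp(-((timeGrid - 0.3)^2) / (2 * 0.6^2))
    nMice <- 2L * params@nMicePerGroup
    nE <- params@trialsPerMouse
    eff <- params@distalEffects

    mouseIds <- sprintf("m%02d", seq_len(nMice))
    groups <- rep(c(0L, 1L), each = params@nMicePerGroup)
    gamma <- rnorm(nMice, 0, params@randomInterceptSd)

    Y <- matrix(0, nMice * nE, nT)
    cov <- vector("list", nMice)
    truthShift <- numeric(nMice * nE)
    r <- 0L
    for (i in seq_len(nMice)) {
      tr <- (seq_len(nE) - 1) / (nE - 1)
      pre <- distalShift(eff, tr, 0, groups[i]) + gamma[i]
      pInc <- plogis(qlogis(0.3) - 1.0 * tr +
                       params@accuracyCoupling * pre)
      outc <- rbinom(nE, 1L, pInc)
      delta <- distalShift(eff, tr, outc, groups[i])
      for (e in seq_len(nE)) {
        r <- r + 1L
        noise <- smoothNoise(nT, params@noiseSmoothS, 10, params@noiseSd)
        Y[r, ] <- template + gamma[i] + delta[e] * distalMask + noise
        truthShift[r] <- delta[e] + gamma[i]
      }
      cov[[i]] <- data.frame(mouse_id = mouseIds[i],
                             trial = seq_len(nE),
                             training_fraction = tr,
                             outcome = outc,
                             stimulation = groups[i],
                             genotype = groups[i])
    }
    covariates <- do.call(rbind, cov)
    dataset <- functionalDataset(
      Y = Y,
      covariates = covariates[, c("training_fraction", "outcome",
                                  "stimulation", "genotype")],
      mouse = covariates$mouse_id,
      time = timeGrid)
    record <- data.frame(mouse_id = covariates$mouse_id,
                         day = (covariates$trial - 1L) %/% 10L + 1L,
                         trial = covariates$trial,
                         outcome = covariates$outcome,
                         stimulation = covariates$stimulation,
                         genotype = covariates$genotype)
    list(dataset = dataset, record = record,
         truth = list(random_intercepts = stats::setNames(gamma, mouseIds),
                      distal_shift = truthShift,
                      effects = eff, distal_mask = distalMask,
                      groups = stats::setNames(groups, mouseIds)))
  })
}
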