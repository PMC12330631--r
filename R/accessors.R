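#' Accessors for photocircuit classes
#'
#' Small generics giving read access to the central objects: synaptic
#' `weights()` of a configuration, `spikeCounts()` and `activityTraces()` of a
#' simulation, `wavelengths()` and `acquisitionRate()` of a spectral record,
#' `coefficientFunctions()` of a functional fit, and `sweepSummary()` of a
#' weight sweep.
#'
#' @param object,x a photocircuit object.
#' @param ... passed on to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spikeCounts", function(object) standardGeneric("spikeCounts"))

#' @rdname accessors
#' @export
setGeneric("activityTraces", function(object) standardGeneric("activityTraces"))

#' @rdname accessors
#' @export
setGeneric("simTime", function(object) standardGeneric("simTime"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("acquisitionRate", function(object) standardGeneric("acquisitionRate"))

#' @rdname accessors
#' @export
setGeneric("sweepSummary", function(object) standardGeneric("sweepSummary"))

#' @rdname accessors
#' @export
setGeneric("coefficientFunctions", function(object) standardGeneric("coefficientFunctions"))

#' @describeIn accessors synaptic weight matrix of a configuration.
#' @export
setMethod("weights", "NetworkConfig", function(object, ...) object@weights)

#' @describeIn accessors per-class spike-count matrix (classes x steps).
setMethod("spikeCounts", "SimulationOutput", function(object) object@spikeCounts)

#' @describeIn accessors smoothed activity matrix of a run.
setMethod("activityTraces", "SimulationOutput", function(object) object@activity)

#' @describeIn accessors run-averaged activity matrix.
setMethod("activityTraces", "ActivityTrace", function(object) object@activity)

#' @describeIn accessors step-time grid (s).
setMethod("simTime", "SimulationOutput", function(object) object@time)

#' @describeIn accessors step-time grid (s).
setMethod("simTime", "ActivityTrace", function(object) object@time)

#' @describeIn accessors wavelength grid (nm) of a spectral record.
setMethod("wavelengths", "SpectralTimeseries", function(object)
  SummarizedExperiment::rowData(object)$wavelength_nm)

#' @describeIn accessors wavelength grid (nm) of reference spectra.
setMethod("wavelengths", "ReferenceSpectra", function(object) object@wavelengths)

#' @describeIn accessors acquisition rate (Hz).
setMethod("acquisitionRate", "SpectralTimeseries", function(object)
  S4Vectors::metadata(object)$rate_hz)

#' @describeIn accessors per-(weight, class) mean and SEM of evoked peaks.
setMethod("sweepSummary", "SweepResult", function(object) {
  pk <- object@peaks
  agg <- do.call(rbind, lapply(split(pk, list(pk$weight, pk$class), drop = TRUE),
    function(d) data.frame(weight = d$weight[1], class = d$class[1],
                           mean = mean(d$peak),
                           sem = sd(d$peak) / sqrt(nrow(d)),
                           n = nrow(d))))
  rownames(agg) <- NULL
  agg[order(-agg$weight, match(agg$class, CELL_CLASSES)), ]
})

#' @describeIn accessors coefficient estimates (terms x timepoints).
setMethod("coefficientFunctions", "FunctionalFit", function(object) object@beta)

#' Coerce results to tidy data frames
#'
#' `as.data.frame` methods giving the tidy (long) export formats: simulation
#' output as (time_s, class, spike_count, activity); sweep results as
#' (weight, class, sim, peak); functional fits as
#' (term, time_s, beta, pw_lower, pw_upper, joint_lower, joint_upper).
#'
#' @param x the object to coerce.
#' @param ... ignored.
#' @return a `data.frame`.
#' @name tidy-coercion
NULL

#' @rdname tidy-coercion
#' @export
setMethod("as.data.frame", "SimulationOutput", function(x, ...) {
  nt <- length(x@time)
  data.frame(
    time_s = rep(x@time, times = 4L),
    class = rep(CELL_CLASSES, each = nt),
    spike_count = as.vector(t(x@spikeCounts)),
    activity = as.vector(t(x@activity)))
})

#' @rdname tidy-coercion
#' @export
setMethod("as.data.frame", "SweepResult", function(x, ...) x@peaks)

#' @rdname tidy-coercion
#' @export
setMethod("as.data.frame", "FunctionalFit", function(x, ...) {
  nt <- length(x@time)
  data.frame(
    term = rep(x@terms, each = nt),
    time_s = rep(x@time, times = length(x@terms)),
    beta = as.vector(t(x@beta)),
    pw_lower = as.vector(t(x@pwLower)),
    pw_upper = as.vector(t(x@pwUpper)),
    joint_lower = as.vector(t(x@jointLower)),
    joint_upper = as.vector(t(x@jointUpper)))
})

#' @export
setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig:", sum(object@nCells), "neurons (",
      paste(sprintf("%s=%d", names(object@nCells), object@nCells),
            collapse = ", "), ")\n")
  cat(sprintf("  dt = %g ms over %g s; stimulation %g Hz in [%g, %g] s\n",
              object@dtMs, object@durationS, object@stimRateHz,
              object@stimWindowS[1], object@stimWindowS[2]))
  cat(sprintf("  w[vHPC->VIP] = %g; threshold %g, reset %g\n",
              object@weights["vHPC", "VIP"], object@spikeThreshold,
              object@resetValue))
})

#' @export
setMethod("show", "SimulationOutput", function(object) {
  cat(sprintf("SimulationOutput: %d steps over %.3g s (seed %d)\n",
              length(object@time), max(object@time), object@seed))
  tot <- as.integer(rowSums(object@spikeCounts))
  names(tot) <- rownames(object@spikeCounts)
  cat("  total spikes:", paste(sprintf("%s=%d", names(tot), tot),
                               collapse = ", "), "\n")
})

#' @export
setMethod("show", "ActivityTrace", function(object) {
  cat(sprintf("ActivityTrace: mean of %d runs, %d steps\n",
              object@nRuns, length(object@time)))
})

#' @export
setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %d weights x %d sims (x %d runs each)\n",
              length(object@weights), object@nSims, object@runsPerSim))
  cat("  weights:", paste(signif(object@weights, 3), collapse = ", "), "\n")
})

#' @export
setMethod("show", "FunctionalFit", function(object) {
  cat(sprintf("FunctionalFit: %d terms x %d timepoints, %d bootstrap replicates\n",
              length(object@terms), length(object@time), object@nBoot))
  cat("  terms:", paste(object@terms, collapse = ", "), "\n")
})

#' @export
setMethod("show", "GeneratorParams", function(object) {
  cat(sprintf("GeneratorParams: %d+%d mice x %d trials, %g Hz acquisition\n",
              object@nMicePerGroup, object@nMicePerGroup,
              object@trialsPerMouse, object@rateHz))
  de <- object@distalEffects
  cat("  distal effects:", paste(sprintf("%s=%g", names(de), de),
                                 collapse = ", "), "\n")
})
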