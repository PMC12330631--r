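#' Read and write model configurations as YAML
#'
#' A [NetworkConfig-class] round-trips through a flat YAML file whose keys
#' mirror the slot names; the weight matrix is stored as a labeled 5x4 block
#' (one row per source).
#'
#' @param config a [NetworkConfig-class].
#' @param path file path.
#' @return `readNetworkConfig` returns a [NetworkConfig-class];
#'   `writeNetworkConfig` returns `path` invisibly.
#' @export
writeNetworkConfig <- function(config, path) {
  W <- config@weights
  lst <- list(
    n_cells = as.list(config@nCells),
    weights = stats::setNames(lapply(rownames(W), function(r) as.list(
      stats::setNames(as.numeric(W[r, ]), colnames(W)))), rownames(W)),
    tau_membrane_ms = config@tauMembraneMs,
    tau_syn_ms = as.list(config@tauSynMs),
    nmda_scale = config@nmdaScale,
    spike_threshold = config@spikeThreshold,
    reset_value = config@resetValue,
    dt_ms = config@dtMs,
    duration_s = config@durationS,
    stim_window_s = as.numeric(config@stimWindowS),
    stim_rate_hz = config@stimRateHz,
    post_stim_decay_tau_ms = config@postStimDecayTauMs,
    vhpc_event_kernel = as.list(config@vhpcKernel),
    vhpc_nmda_kernel = as.list(config@vhpcNmdaKernel),
    vhpc_noise_rate_hz = config@vhpcNoiseRateHz,
    neuron_noise = list(rate_hz = config@neuronNoise$rate_hz,
                        amplitude = as.list(config@neuronNoise$amplitude),
                        tau_ms = config@neuronNoise$tau_ms,
                        length_steps = config@neuronNoise$length_steps),
    pyr_connection_prob = config@pyrConnectionProb,
    smoothing_sigma_ms = config@smoothingSigmaMs)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeNetworkConfig
#' @export
readNetworkConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  W <- do.call(rbind, lapply(WEIGHT_SOURCES, function(r)
    unlist(lst$weights[[r]])[CELL_CLASSES]))
  dimnames(W) <- list(WEIGHT_SOURCES, CELL_CLASSES)
  networkConfig(
    weights = W,
    nCells = unlist(lst$n_cells)[CELL_CLASSES],
    tauMembraneMs = lst$tau_membrane_ms,
    tauSynMs = unlist(lst$tau_syn_ms)[c("VIP", "SST", "PV", "PYR_AMPA",
                                        "PYR_NMDA")],
    nmdaScale = lst$nmda_scale,
    spikeThreshold = lst$spike_threshold,
    resetValue = lst$reset_value,
    dtMs = lst$dt_ms,
    durationS = lst$duration_s,
    stimWindowS = as.numeric(unlist(lst$stim_window_s)),
    stimRateHz = lst$stim_rate_hz,
    postStimDecayTauMs = lst$post_stim_decay_tau_ms,
    vhpcKernel = unlist(lst$vhpc_event_kernel)[c("tau_ms", "length_steps")],
    vhpcNmdaKernel = unlist(lst$vhpc_nmda_kernel)[c("tau_ms", "length_steps")],
    vhpcNoiseRateHz = lst$vhpc_noise_rate_hz,
    neuronNoise = list(rate_hz = lst$neuron_noise$rate_hz,
                       amplitude = unlist(lst$neuron_noise$amplitude)[CELL_CLASSES],
                       tau_ms = lst$neuron_noise$tau_ms,
                       length_steps = lst$neuron_noise$length_steps),
    pyrConnectionProb = lst$pyr_connection_prob,
    smoothingSigmaMs = lst$smoothing_sigma_ms)
}

#' Write a spectral record and trial table as plain-text files
#'
#' `writeSpectralCsv` stores a [SpectralTimeseries-class] as CSV (first
#' column the wavelength grid, remaining columns one frame each; the header
#' row carries the acquisition rate); `readSpectralCsv` inverts it.
#'
#' @param spec a [SpectralTimeseries-class].
#' @param path file path.
#' @export
writeSpectralCsv <- function(spec, path) {
  counts <- SummarizedExperiment::assay(spec, "counts")
  df <- data.frame(wavelength_nm = wavelengths(spec), counts,
                   check.names = FALSE)
  names(df)[-1] <- sprintf("f%d", seq_len(ncol(counts)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%g t0=%g", acquisitionRate(spec),
                     S4Vectors::metadata(spec)$t0), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectralCsv
#' @export
readSpectralCsv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("rate_hz=([0-9.]+) t0=([0-9.eE+-]+)", hdr))[[1]]
  df <- utils::read.csv(path, skip = 1, check.names = FALSE)
  spectralTimeseries(as.matrix(df[, -1, drop = FALSE]),
                     wavelengths = df[[1]],
                     rateHz = as.numeric(m[2]), t0 = as.numeric(m[3]))
}
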