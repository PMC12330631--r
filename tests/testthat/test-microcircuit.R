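test_that("default weight matrix matches the published table", {
  W <- defaultWeightMatrix()
  expect_identical(dim(W), c(5L, 4L))
  expect_equal(W["vHPC", ], c(VIP = 1.6, SST = 1, PV = 1.6, PYR = 1))
  expect_equal(W["VIP", ], c(VIP = 0, SST = 1, PV = 0.05, PYR = 0))
  expect_equal(W["SST", ], c(VIP = 1, SST = 0, PV = 0.75, PYR = 0.75))
  expect_equal(W["PV", ], c(VIP = 0, SST = 0, PV = 2.25, PYR = 2))
  expect_equal(W["PYR", ], c(VIP = 0.8, SST = 8, PV = 0.8, PYR = 0.25))
})

test_that("configuration validity catches bad inputs", {
  expect_error(networkConfig(dtMs = -0.1), "positive")
  expect_error(networkConfig(stimWindowS = c(3, 2)), "interval")
  expect_error(networkConfig(nmdaScale = 1.5), "nmdaScale")
  W <- defaultWeightMatrix(); W[1, 1] <- -1
  expect_error(networkConfig(weights = W), "non-negative")
})

test_that("pyramidal connectivity honors p, diagonal and seed", {
  expect_true(all(buildPyrConnectivity(10, 0, seed = 1) == 0))
  M1 <- buildPyrConnectivity(3, 1, seed = 1)
  expect_equal(sum(M1), 6)
  expect_true(all(diag(M1) == 0))
  expect_identical(buildPyrConnectivity(20, 0.2, seed = 42),
                   buildPyrConnectivity(20, 0.2, seed = 42))
  expect_error(buildPyrConnectivity(5, 1.2), "probability")
  # mean off-diagonal density approaches p (binomial SE over many seeds)
  dens <- vapply(1:300, function(s) {
    M <- buildPyrConnectivity(20, 0.2, seed = s)
    sum(M) / (20 * 19)
  }, numeric(1))
  se <- sqrt(0.2 * 0.8 / (20 * 19 * 300))
  expect_lt(abs(mean(dens) - 0.2), 3 * se)
})

test_that("vHPC raster follows the stimulation rate profile", {
  cfg <- networkConfig()
  r <- sampleVhpcRaster(cfg, seed = 1)
  tm <- (seq_along(r)) * 1e-4
  expect_true(all(r[tm <= 2] == 0))
  # closed-form decayed rate 1 s after stimulation offset
  expect_equal(vhpcRate(cfg, 4), 100 * exp(-1))
  # expected stimulation-window count is rate * 1 s
  counts <- vapply(1:200, function(s) {
    r <- sampleVhpcRaster(cfg, seed = s)
    sum(r[tm > 2 & tm <= 3])
  }, numeric(1))
  se <- sqrt(100 * (1 - 0.01) / 200)
  expect_lt(abs(mean(counts) - 100), 3 * se)
  # undersampled configuration is rejected
  expect_error(sampleVhpcRaster(networkConfig(stimRateHz = 2e4), seed = 1),
               "undersampled")
})

test_that("exponential kernel filtration matches its analytic form", {
  x <- numeric(500); x[20] <- 1
  y <- expKernelFilter(x, 1, tauMs = 8, lengthSteps = 400, dtMs = 0.1)
  expect_equal(y[20 + 80], exp(-1), tolerance = 1e-12)
  y40 <- expKernelFilter(x, 2.5, tauMs = 8, lengthSteps = 40, dtMs = 0.1)
  expect_equal(y40[20], 2.5)
  expect_lt(abs(y40[20 + 41]), 1e-12)  # beyond the 40-step support
  # linearity: superposition of overlapping events
  x2 <- numeric(500); x2[25] <- 1
  both <- expKernelFilter(x + x2, 1, 8, 40, 0.1)
  expect_equal(both, expKernelFilter(x, 1, 8, 40, 0.1) +
                 expKernelFilter(x2, 1, 8, 40, 0.1), tolerance = 1e-12)
  # against the brute-force convolution oracle
  set.seed(9)
  xr <- rbinom(300, 1, 0.05)
  expect_equal(expKernelFilter(xr, 1.3, 8, 40, 0.1),
               convOracle(xr, 1.3, 8, 40, 0.1), tolerance = 1e-10)
})

test_that("single-step update: decay, spiking, reset and output increments", {
  cfg <- tinyConfig()
  M <- matrix(0L, 20, 20)
  st <- photocircuit:::newNetworkState(cfg)
  zero <- list(ampa = 0, nmda = 0, noise = 0, neuron = numeric(36))
  # pure decay, no drive
  st$v[] <- 5
  r <- stepNetwork(st, zero, cfg, M)
  expect_equal(r$state$v, rep(5 * exp(-0.01), 36), tolerance = 1e-12)
  expect_false(any(r$spiked))
  # threshold crossing spikes now, resets on the following step
  st2 <- photocircuit:::newNetworkState(cfg)
  st2$v[1] <- 10.5 / exp(-0.01)
  r2 <- stepNetwork(st2, zero, cfg, M)
  expect_true(r2$spiked[1])
  r3 <- stepNetwork(r2$state, zero, cfg, M)
  expect_equal(r3$state$v[1], -10)
  # class output increments by the spiking proportion (3 of 6 SST -> 0.5)
  st3 <- photocircuit:::newNetworkState(cfg)
  sstIdx <- which(photocircuit:::classIndex(cfg) == "SST")
  st3$v[sstIdx[1:3]] <- 11 / exp(-0.01)
  r4 <- stepNetwork(st3, zero, cfg, M)
  expect_equal(unname(r4$state$out["SST"]), 0.5)
})

test_that("subthreshold voltage equals kernel-filtered drive convolved with membrane decay", {
  # closed-form limit: infinite threshold, no noise, a single vHPC event
  cfg <- networkConfig(durationS = 0.1, stimWindowS = c(0.01, 0.09),
                       spikeThreshold = Inf, resetValue = -10,
                       stimRateHz = 0, vhpcNoiseRateHz = 0,
                       neuronNoise = list(rate_hz = 0,
                                          amplitude = c(VIP = 1, SST = 1,
                                                        PV = 1.2, PYR = 1),
                                          tau_ms = 8, length_steps = 40))
  n <- 1000
  raster <- numeric(n); raster[100] <- 1
  drive <- list(
    ampa = expKernelFilter(raster, 1, 8, 40, 0.1),
    nmda = expKernelFilter(raster, 1, 80, 400, 0.1),
    noise = numeric(n),
    neuron = matrix(0, 36, n),
    raster = raster)
  M <- matrix(0L, 20, 20)
  eng <- runEngine(cfg, drive, M, recordV = TRUE)
  # brute-force oracle: v[t] = sum_s vdecay^(t-s) * dt * input[s-1]
  W <- weights(cfg)
  vdecay <- exp(-0.1 / 10)
  inp <- W["vHPC", "VIP"] * (drive$ampa + 0.3 * drive$nmda)
  vOracle <- numeric(n)
  for (t in 2:n) vOracle[t] <- vOracle[t - 1] * vdecay + 0.1 * inp[t - 1]
  expect_lt(max(abs(eng$v[1, ] - vOracle)), 1e-9)
  expect_true(all(eng$spikeCounts == 0))
})

test_that("compiled engine and per-step reference agree with and without spikes", {
  cfg <- networkConfig(durationS = 0.1, stimWindowS = c(0.02, 0.08))
  drive <- buildExternalDrive(cfg, seed = 5)
  M <- buildPyrConnectivity(20, 0.2, seed = 6)
  ref <- runSimulationReference(cfg, drive, M, recordV = TRUE)
  eng <- runEngine(cfg, drive, M, recordV = TRUE)
  expect_gt(sum(ref$spikeCounts), 0)  # the with-spike regime is exercised
  expect_lt(max(abs(ref$v - eng$v)), 1e-9)
  expect_equal(ref$spikeCounts, eng$spikeCounts)
  cfgNS <- networkConfig(durationS = 0.1, stimWindowS = c(0.02, 0.08),
                         spikeThreshold = 1e9)
  refNS <- runSimulationReference(cfgNS, drive, M, recordV = TRUE)
  engNS <- runEngine(cfgNS, drive, M, recordV = TRUE)
  expect_lt(max(abs(refNS$v - engNS$v)), 1e-9)
  expect_true(all(refNS$spikeCounts == 0))
})

test_that("silence, determinism and spike conservation hold for full runs", {
  simA <- runSimulation(tinyConfig(), seed = 3)
  simB <- runSimulation(tinyConfig(), seed = 3)
  expect_identical(spikeCounts(simA), spikeCounts(simB))
  simC <- runSimulation(tinyConfig(), seed = 4)
  expect_false(identical(spikeCounts(simA), spikeCounts(simC)))
  # zero drives from zero state -> no spikes anywhere
  simZ <- runSimulation(silentConfig(), seed = 1)
  expect_true(all(spikeCounts(simZ) == 0))
  # Gaussian smoothing is mass-preserving away from edges
  expect_equal(sum(activityTraces(simA)), sum(spikeCounts(simA)),
               tolerance = 0.02)
})

test_that("subthreshold voltage is linear in the drive amplitude", {
  cfg <- networkConfig(durationS = 0.05, stimWindowS = c(0.01, 0.04),
                       spikeThreshold = Inf)
  drive <- buildExternalDrive(cfg, seed = 8)
  M <- buildPyrConnectivity(20, 0.2, seed = 8)
  scale <- function(d, c) list(ampa = d$ampa * c, nmda = d$nmda * c,
                               noise = d$noise * c, neuron = d$neuron * c)
  v1 <- runEngine(cfg, drive, M, recordV = TRUE)$v
  v2 <- runEngine(cfg, scale(drive, 0.3), M, recordV = TRUE)$v
  expect_equal(v2, 0.3 * v1, tolerance = 1e-9)
})

test_that("condition averaging reduces variance and keeps the grid", {
  cfg <- tinyConfig()
  tr1 <- simulateCondition(cfg, nRuns = 1, seed = 21)
  expect_equal(dim(activityTraces(tr1)), c(4L, 5000L))
  # averaging across runs shrinks between-simulation variability
  single <- vapply(1:8, function(s)
    evokedPeak(activityTraces(simulateCondition(cfg, 1, seed = s))["VIP", ],
               simTime(tr1), c(0.02, 0.1), c(0.1, 0.5)), numeric(1))
  avg5 <- vapply(1:8, function(s)
    evokedPeak(activityTraces(simulateCondition(cfg, 5, seed = 100 + s))["VIP", ],
               simTime(tr1), c(0.02, 0.1), c(0.1, 0.5)), numeric(1))
  expect_lt(var(avg5), var(single))
})

test_that("evoked peak is the baseline-subtracted response maximum", {
  tm <- seq(0.01, 10, by = 0.01)
  expect_equal(evokedPeak(rep(2, length(tm)), tm), 0)
  tr <- rep(1, length(tm))
  tr[tm > 4 & tm < 4.5] <- 3
  expect_equal(evokedPeak(tr, tm), 2)
  expect_error(evokedPeak(tr, tm, baselineWindow = c(20, 30)), "window")
})

test_that("configuration round-trips through YAML", {
  cfg <- networkConfig(stimRateHz = 80)
  path <- tempfile(fileext = ".yaml")
  writeNetworkConfig(cfg, path)
  cfg2 <- readNetworkConfig(path)
  expect_equal(weights(cfg2), weights(cfg))
  expect_equal(cfg2@stimRateHz, 80)
  expect_equal(cfg2@tauSynMs, cfg@tauSynMs)
  expect_equal(cfg2@neuronNoise$amplitude, cfg@neuronNoise$amplitude)
})
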