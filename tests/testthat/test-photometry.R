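test_that("band summation includes the closed band edges", {
  spec <- spectralTimeseries(matrix(1, 42, 5), wavelengths = 500:541,
                             rateHz = 40)
  expect_equal(bandSummedSignal(spec, c(500, 541)), rep(42, 5))
  expect_equal(bandSummedSignal(spec, c(500, 500)), rep(1, 5))
  expect_error(bandSummedSignal(spec, c(450, 541)), "outside")
})

test_that("unmixing inverts an exact mixture and matches projections", {
  refs <- makeReferenceSpectra()
  co <- rbind(gcamp = c(3, 1, 0.5), tdtomato = c(5, 2, 4),
              background = c(0, 0, 0))
  spec <- mixSpectra(co, refs, rateHz = 20)
  um <- linearUnmix(spec, refs)
  expect_equal(um$coefficients[c("gcamp", "tdtomato"), ],
               co[c("gcamp", "tdtomato"), ], tolerance = 1e-9)
  expect_lt(max(um$residuals), 1e-9)
  # orthogonal references: coefficients equal per-reference projections
  g <- seq(1, 10, length.out = 6)
  R <- cbind(a = c(1, 0, 0, 0, 0, 0), b = c(0, 1, 0, 0, 0, 0))
  orth <- new("ReferenceSpectra", wavelengths = g, spectra = R)
  y <- matrix(c(2, 7, 1, 1, 1, 1), ncol = 1)
  specO <- spectralTimeseries(y, g, rateHz = 20)
  umO <- linearUnmix(specO, orth, background = FALSE)
  expect_equal(as.numeric(umO$coefficients), as.numeric(t(R) %*% y))
  # rank-deficient reference matrix is refused
  dup <- new("ReferenceSpectra", wavelengths = refs@wavelengths,
             spectra = cbind(gcamp = refs@spectra[, 1],
                             tdtomato = refs@spectra[, 1]))
  expect_error(linearUnmix(spec, dup), "rank deficient")
})

test_that("unmixing recovers coefficient traces under Poisson noise", {
  # high-count regime: photon noise small relative to the coefficient dynamics
  params <- generatorParams(baselineCounts = c(gcamp = 6000, tdtomato = 4000))
  ses <- simulateSwmSession(params, seed = 2, nTrials = 3)
  um <- linearUnmix(ses$spectra, makeReferenceSpectra())
  truth <- ses$truth$coefficients
  expect_gt(cor(um$coefficients["gcamp", ], truth["gcamp", ]), 0.99)
  expect_gt(cor(um$coefficients["tdtomato", ], truth["tdtomato", ]), 0.99)
})

test_that("linear detrending removes the slope and preserves the mean", {
  t <- 1:200
  x <- 4 + 0.03 * t + rnorm(200, sd = 1e-6)
  y <- detrendLinear(x)
  expect_equal(mean(y), mean(x))
  refit <- coef(lm(y ~ t))[2]
  expect_lt(abs(refit), 1e-10)
  flat <- rep(2.5, 50)
  expect_equal(detrendLinear(flat), flat)
  expect_error(detrendLinear(1), "2 samples")
})

test_that("block-mean downsampling averages non-overlapping blocks", {
  expect_equal(downsampleMean(1:8, 40, 10), c(2.5, 6.5))
  expect_equal(downsampleMean(rep(7, 20), 20, 10), rep(7, 10))
  expect_length(downsampleMean(rnorm(40), 20, 10), 20)
  expect_error(downsampleMean(1:8, 30, 8), "integer multiple")
})

test_that("per-trial dF/F and peak response behave on known signals", {
  rate <- 10
  f <- rep(100, 40 * rate)
  expect_equal(dffPerTrial(f, rate, trialStartS = 0), rep(0, 300))
  f2 <- rep(100, 40 * rate)
  f2[(10 * rate + 1):(30 * rate)] <- 200  # doubles after the baseline period
  d2 <- dffPerTrial(f2, rate, trialStartS = 0)
  expect_equal(max(d2), 100)
  # injected 7.5% bump at 12 s is returned by the 10-15-s peak
  f3 <- rep(100, 40 * rate)
  f3[12 * rate + 1] <- 107.5
  expect_equal(peakResponse(dffPerTrial(f3, rate, 0), rate), 7.5)
  expect_equal(peakResponse(rep(0, 200), rate), 0)
  expect_error(dffPerTrial(rep(0, 400), rate, 0), "baseline")
})

test_that("ratio z-scores cancel shared artifacts and are standardized", {
  set.seed(4)
  n <- 600
  g <- 100 + 5 * sin(seq_len(n) / 20) + rnorm(n)
  td <- rep(80, n)
  m <- exp(0.3 * sin(seq_len(n) / 35))   # strictly positive shared artifact
  bounds <- data.frame(start = c(0, 30), end = c(30, 60))
  zPlain <- ratioZscoreTrials(g, td, bounds)
  zArt <- ratioZscoreTrials(g * m, td * m, bounds)
  expect_equal(zArt$z, zPlain$z, tolerance = 1e-12)
  for (tr in 1:2) {
    zi <- zPlain$z[zPlain$trial == tr]
    expect_lt(abs(mean(zi)), 1e-10)
    expect_lt(abs(sd(zi) - 1), 1e-10)
  }
  # degenerate trials are excluded with a warning
  expect_warning(res <- ratioZscoreTrials(rep(1, 100), rep(1, 100),
                                          data.frame(start = 0, end = 10)),
                 "zero-variance")
  expect_equal(nrow(res), 0)
})

test_that("distal-delay scores average the 2 s before choice start", {
  z <- rep(0, 400)
  z[181:200] <- 0.7  # samples at 18.0-19.9 s
  expect_equal(distalDelayScore(z, 20), 0.7)
  expect_equal(distalDelayScore(rep(0, 400), 20), 0)
  expect_warning(s <- distalDelayScore(z, 0.5), "flagged")
  expect_true(is.na(s))
})

test_that("peri-event averaging recovers a stereotyped template", {
  rate <- 10
  template <- sin(seq(-pi, pi, length.out = 21))
  z <- rep(0, 1000)
  events <- c(20, 40, 60)
  for (ev in events) {
    c0 <- ev * rate + 1
    z[(c0 - 10):(c0 + 10)] <- z[(c0 - 10):(c0 + 10)] + template
  }
  pe <- periEventAverage(z, events, windowS = c(-1, 1), rateHz = rate)
  expect_equal(pe$mean, template, tolerance = 1e-12)
  expect_equal(pe$n, 3L)
  # unit-range normalization maps each window to [-1, 1]
  peN <- periEventAverage(z, events, windowS = c(-1, 1), rateHz = rate,
                          normalizeUnitRange = TRUE)
  expect_equal(max(peN$mean), 1)
  expect_equal(min(peN$mean), -1)
  # single event returns the window itself
  pe1 <- periEventAverage(z, events[1], windowS = c(-1, 1), rateHz = rate)
  expect_equal(pe1$mean, z[(events[1] * rate + 1 - 10):(events[1] * rate + 1 + 10)])
  expect_warning(periEventAverage(z, c(0.1, 50), windowS = c(-5, 5)),
                 "skipped")
})

test_that("lagged cross-correlation finds leads, lags and inversions", {
  set.seed(11)
  ca <- as.numeric(arima.sim(list(ar = 0.8), 800))
  vel <- c(rep(0, 10), ca)[1:800]   # velocity follows calcium by 10 samples
  cc <- crosscorrLagged(ca, vel)
  expect_equal(cc$lag[which.max(cc$r)], 10)
  expect_equal(nrow(cc), 101)
  ccNeg <- crosscorrLagged(ca, -ca)
  expect_equal(ccNeg$r[ccNeg$lag == 0], -1)
  # independent white series stay inside the null envelope
  a <- rnorm(2000); b <- rnorm(2000)
  ccN <- crosscorrLagged(a, b)
  expect_lt(max(abs(ccN$r)), 4 / sqrt(2000 - 50))
  # zero-variance input is reported as undefined
  ccZ <- crosscorrLagged(rep(1, 200), rnorm(200))
  expect_true(all(is.na(ccZ$r)))
})

test_that("spectral records round-trip through the CSV format", {
  spec <- spectralTimeseries(matrix(rpois(60, 20), 6, 10),
                             wavelengths = seq(500, 600, length.out = 6),
                             rateHz = 20, t0 = 1.5)
  path <- tempfile(fileext = ".csv")
  writeSpectralCsv(spec, path)
  back <- readSpectralCsv(path)
  expect_equal(unname(SummarizedExperiment::assay(back, "counts")),
               unname(SummarizedExperiment::assay(spec, "counts")))
  expect_equal(wavelengths(back), wavelengths(spec))
  expect_equal(acquisitionRate(back), 20)
  expect_equal(S4Vectors::metadata(back)$t0, 1.5)
})
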