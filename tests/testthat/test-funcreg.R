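smallCohort <- function(seed = 1, ...) {
  simulateCohort(generatorParams(nMicePerGroup = 4L, trialsPerMouse = 30L,
                                 ...), seed = seed)
}

test_that("the five model designs have the published shapes and codings", {
  coh <- smallCohort()
  d1 <- buildDesign(coh$dataset, 1)
  expect_equal(d1$terms, c("(Intercept)", "stimulation"))
  d2 <- buildDesign(coh$dataset, 2)
  expect_equal(d2$terms, c("(Intercept)", "outcome"))
  d3 <- buildDesign(coh$dataset, 3)
  expect_equal(d3$terms, c("(Intercept)", "training_fraction", "outcome",
                           "training_fraction:outcome"))
  # interaction column is the product of its mains
  expect_equal(d3$X[, 4], d3$X[, 2] * d3$X[, 3])
  d4 <- buildDesign(coh$dataset, 4)
  d5 <- buildDesign(coh$dataset, 5)
  expect_equal(sub("genotype", "stimulation", d5$terms), d4$terms)
  expect_error(modelSpec(6), "modelId")
  # missing covariate is reported by name
  ds <- coh$dataset
  ds@covariates$genotype <- NULL
  expect_error(buildDesign(ds, 5), "genotype")
})

test_that("training is coded 0 at the first and 1 at the last trial per mouse", {
  coh <- smallCohort()
  tr <- split(coh$dataset@covariates$training_fraction, coh$dataset@mouse)
  for (v in tr) {
    expect_equal(v[1], 0)
    expect_equal(v[length(v)], 1)
  }
})

test_that("pointwise fits reduce to group-mean differences and nulls", {
  # single timepoint, two groups: coefficient equals the mean difference
  Y <- matrix(c(rnorm(20, 0), rnorm(20, 1.3)), ncol = 1)
  covs <- data.frame(stimulation = rep(c(0, 1), each = 20),
                     outcome = 0, training_fraction = 0, genotype = 0)
  ds <- functionalDataset(Y, covs, mouse = rep(sprintf("m%d", 1:8), 5),
                          time = 0)
  fit <- fitPointwise(ds, 1)
  expect_equal(unname(fit$beta["stimulation", 1]),
               mean(Y[21:40, 1]) - mean(Y[1:20, 1]))
  # null data: coefficients near zero relative to their scatter
  coh <- smallCohort(seed = 5)
  f <- fitPointwise(coh$dataset, 4)
  expect_lt(max(abs(rowMeans(f$beta)[-1])), 0.3)
})

test_that("rank-deficient designs are refused with the collinear term named", {
  coh <- smallCohort()
  ds <- coh$dataset
  ds@covariates$outcome <- 1  # collinear with the intercept
  expect_error(fitPointwise(ds, 3), "collinear")
})

test_that("coefficient estimates ignore trial order and cluster labels", {
  coh <- smallCohort(seed = 7)
  f0 <- fitPointwise(coh$dataset, 4)
  perm <- sample(nrow(coh$dataset@Y))
  dsP <- functionalDataset(coh$dataset@Y[perm, ],
                           coh$dataset@covariates[perm, ],
                           coh$dataset@mouse[perm], coh$dataset@time)
  expect_equal(fitPointwise(dsP, 4)$beta, f0$beta)
  relab <- factor(paste0("x_", coh$dataset@mouse))
  dsR <- functionalDataset(coh$dataset@Y, coh$dataset@covariates,
                           relab, coh$dataset@time)
  expect_equal(fitPointwise(dsR, 4)$beta, f0$beta)
})

test_that("bootstrap bands are reproducible, nested and sized correctly", {
  coh <- smallCohort(seed = 3)
  fit <- clusterBootstrapCI(coh$dataset, 4, nBoot = 200, seed = 9)
  fit2 <- clusterBootstrapCI(coh$dataset, 4, nBoot = 200, seed = 9)
  expect_equal(fit@boot, fit2@boot)
  expect_equal(dim(fit@boot), c(200L, 4L, length(coh$dataset@time)))
  # joint bands contain pointwise bands everywhere (validity also enforces)
  expect_true(all(fit@jointLower <= fit@pwLower + 1e-12))
  expect_true(all(fit@jointUpper >= fit@pwUpper - 1e-12))
  expect_error(clusterBootstrapCI(coh$dataset, 4, nBoot = 50), "200")
})

test_that("an injected distal-window interaction is recovered and localized", {
  params <- generatorParams(distalEffects = c(outcome = 0, training = 0,
                                              group = 0,
                                              training_x_group = 0.5))
  coh <- simulateCohort(params, seed = 42)
  fit <- clusterBootstrapCI(coh$dataset, 4, nBoot = 200, seed = 1)
  term <- "training_fraction:stimulation"
  mask <- coh$truth$distal_mask
  # recovery inside the injected window
  expect_lt(abs(mean(fit@beta[term, mask]) - 0.5), 0.15)
  # and near zero outside it
  expect_lt(abs(mean(fit@beta[term, !mask])), 0.15)
  si <- significantIntervals(fit, term)
  expect_true(any(si$sign == "+" & si$start <= -0.1 & si$end >= -1.9))
})

test_that("significant intervals are extracted with signs from joint bands", {
  tmGrid <- seq(0, 9.9, by = 0.1)
  p <- 2L; nT <- length(tmGrid)
  beta <- matrix(0, p, nT, dimnames = list(c("(Intercept)", "eff"), NULL))
  lo <- beta - 1; hi <- beta + 1
  # effect band above zero exactly on [3, 4], below on [7, 8]
  up <- tmGrid >= 3 & tmGrid <= 4
  dn <- tmGrid >= 7 & tmGrid <= 8
  lo["eff", up] <- 0.2; hi["eff", up] <- 1
  lo["eff", dn] <- -1;  hi["eff", dn] <- -0.2
  fit <- new("FunctionalFit", terms = rownames(beta), time = tmGrid,
             beta = beta, pwLower = lo, pwUpper = hi,
             jointLower = lo, jointUpper = hi,
             boot = array(0, c(200, p, nT)), nBoot = 200L, seed = 1L)
  si <- significantIntervals(fit, "eff")
  expect_equal(si$start, c(3, 7))
  expect_equal(si$end, c(4, 8))
  expect_equal(si$sign, c("+", "-"))
  expect_equal(nrow(significantIntervals(fit, "(Intercept)")), 0)
  expect_error(significantIntervals(fit, "nope"), "unknown term")
})

test_that("with one cluster per trial the bands match an ordinary bootstrap", {
  # when every trial is its own cluster, cluster resampling IS the ordinary
  # nonparametric bootstrap of trials
  set.seed(8)
  n <- 120
  Y <- matrix(rnorm(n * 5, mean = 0.4), n, 5)
  covs <- data.frame(stimulation = rep(c(0, 1), each = n / 2),
                     outcome = 0, training_fraction = 0, genotype = 0)
  ds <- functionalDataset(Y, covs, mouse = sprintf("t%03d", 1:n),
                          time = seq(0, 0.4, by = 0.1))
  fit <- clusterBootstrapCI(ds, 1, nBoot = 400, seed = 2)
  # compare the bootstrap SE of the group effect with its analytic SE
  analytic <- sqrt(4 / n + 4 / n) / sqrt(2)  # sd 1, two groups of n/2
  bootSd <- apply(fit@boot[, 2, ], 2, sd)
  expect_lt(max(abs(bootSd - analytic) / analytic), 0.35)
  # and pointwise bands should cover the truth (0) at all 5 timepoints here
  expect_true(all(fit@pwLower["stimulation", ] <= 0.5))
})
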