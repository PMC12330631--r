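#' The five trial-level functional model specifications
#'
#' Returns the requested model specification for pointwise functional
#' regression of trial-level calcium signals:
#' \describe{
#'   \item{1}{`~ stimulation`, random intercept per mouse.}
#'   \item{2}{`~ outcome`, random intercept + outcome slope per mouse.}
#'   \item{3}{`~ training_fraction * outcome`, random intercept + outcome
#'     slope per mouse.}
#'   \item{4}{`~ training_fraction * stimulation`, random intercept per mouse.}
#'   \item{5}{`~ training_fraction * genotype`, random intercept per mouse.}
#' }
#' Training is continuous in \[0, 1\] (0 = first, 1 = last trial of a mouse);
#' outcome, stimulation and genotype are 0/1 coded. The random-effect
#' structure is a descriptor only: uncertainty from mouse-level heterogeneity
#' is absorbed by the clustered bootstrap of [clusterBootstrapCI()], not by a
#' likelihood fit.
#'
#' @param modelId integer 1-5.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(modelId) {
  specs <- list(
    list(fixed = ~stimulation, random = "(1 | mouse)"),
    list(fixed = ~outcome, random = "(outcome | mouse)"),
    list(fixed = ~training_fraction * outcome, random = "(outcome | mouse)"),
    list(fixed = ~training_fraction * stimulation, random = "(1 | mouse)"),
    list(fixed = ~training_fraction * genotype, random = "(1 | mouse)"))
  if (!modelId %in% 1:5) stop("modelId must be 1, 2, 3, 4 or 5")
  s <- specs[[modelId]]
  new("ModelSpec", modelId = as.integer(modelId), fixed = s$fixed,
      random = s$random)
}

#' Build the fixed-effect design matrix for a model specification
#'
#' @param dataset a [FunctionalDataset-class].
#' @param spec a [ModelSpec-class] (or an integer model id).
#' @return list with `X` (trials x terms design matrix, intercept first) and
#'   `terms` (column names).
#' @export
buildDesign <- function(dataset, spec) {
  if (is.numeric(spec)) spec <- modelSpec(spec)
  need <- all.vars(spec@fixed)
  missing <- setdiff(need, names(dataset@covariates))
  if (length(missing))
    stop("missing covariate(s) for model ", spec@modelId, ": ",
         paste(missing, collapse = ", "))
  X <- stats::model.matrix(spec@fixed, data = dataset@covariates)
  list(X = X, terms = colnames(X))
}

#' Pointwise least-squares coefficient functions
#'
#' Fits, independently at every timepoint, ordinary least squares of the
#' trial-level signal on the model's fixed-effect design, returning the
#' coefficient estimate of each term as a function of peri-event time.
#' Mouse-level random-effect structure does not enter the point estimates;
#' it is absorbed by the clustered bootstrap when bands are required.
#'
#' @param dataset a [FunctionalDataset-class].
#' @param spec a [ModelSpec-class] or model id.
#' @return list with `beta` (terms x timepoints), `terms`, `time`.
#' @export
fitPointwise <- function(dataset, spec) {
  d <- buildDesign(dataset, spec)
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) {
    drop <- d$terms[qrX$pivot[(qrX$rank + 1):ncol(d$X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qrX, dataset@Y)
  rownames(beta) <- d$terms
  list(beta = beta, terms = d$terms, time = dataset@time)
}

# cluster-robust (CR0) standard errors of the pointwise OLS coefficients,
# vectorized over timepoints: var_k(t) = sum_g [ (X'X)^-1 X_g' e_g(t) ]_k^2
clusterRobustSE <- function(X, Y, beta, rowsList) {
  H <- chol2inv(chol(crossprod(X)))
  E <- Y - X %*% beta
  v <- matrix(0, ncol(X), ncol(Y))
  for (rows in rowsList) {
    U <- (H %*% t(X[rows, , drop = FALSE])) %*% E[rows, , drop = FALSE]
    v <- v + U^2
  }
  sqrt(v)
}

#' Mouse-clustered bootstrap-t confidence bands for coefficient functions
#'
#' Resamples mice (clusters) with replacement and refits the pointwise
#' least-squares coefficients on each replicate. Uncertainty is summarized
#' through studentized pivots: each replicate's coefficient deviation is
#' divided by that replicate's cluster-robust (CR0) standard error, so the
#' heavier-than-Gaussian tails that a handful of clusters produce are
#' reflected in the interval quantiles (with 12 mice, raw replicate
#' percentiles behave like a normal approximation to a t statistic with
#' 5-11 degrees of freedom and under-cover by several percent; the
#' studentized construction restores nominal 95% coverage, which the null
#' calibration simulations in the test suite check directly).
#'
#' Pointwise 95% bands are `betahat - q_{97.5/2.5}(pivots_t) * se(t)` per
#' timepoint. Joint (simultaneous) 95% bands use, per term, the 95th
#' percentile over replicates of the maximum over time of the replicate
#' deviation studentized by the bootstrap standard deviation (the
#' max-statistic construction), widened where necessary so they always
#' contain the pointwise band. Time intervals where the joint
#' band excludes zero are therefore adjusted for multiplicity. A replicate
#' that collapses to fewer than two distinct clusters or to a rank-deficient
#' design is redrawn (up to 100 retries, with a message).
#'
#' @param dataset a [FunctionalDataset-class] with at least two clusters.
#' @param spec a [ModelSpec-class] or model id.
#' @param nBoot number of bootstrap replicates (>= 200).
#' @param seed integer seed.
#' @return a [FunctionalFit-class].
#' @export
clusterBootstrapCI <- function(dataset, spec, nBoot = 1000L, seed = 1L) {
  if (nBoot < 200L) stop("nBoot must be >= 200")
  if (is.numeric(spec)) spec <- modelSpec(spec)
  full <- fitPointwise(dataset, spec)
  p <- length(full$terms)
  nT <- length(dataset@time)
  mouse <- droplevels(dataset@mouse)
  mice <- levels(mouse)
  if (length(mice) < 2L) stop("at least two clusters are required")
  rowsOf <- split(seq_len(nrow(dataset@Y)), mouse)
  X0 <- stats::model.matrix(spec@fixed, data = dataset@covariates)
  se0 <- clusterRobustSE(X0, dataset@Y, full$beta, rowsOf)
  se0[se0 == 0] <- .Machine$double.eps

  boot <- array(NA_real_, dim = c(nBoot, p, nT))
  piv <- array(NA_real_, dim = c(nBoot, p, nT))
  withSeed(seed, {
    redraws <- 0L
    for (b in seq_len(nBoot)) {
      repeat {
        draw <- sample(mice, length(mice), replace = TRUE)
        if (length(unique(draw)) < 2L) {
          redraws <- redraws + 1L
          if (redraws > 100L) stop("too many degenerate bootstrap replicates")
          next
        }
        idx <- unlist(rowsOf[draw], use.names = FALSE)
        Xb <- X0[idx, , drop = FALSE]
        qrX <- qr(Xb)
        if (qrX$rank < p) {
          redraws <- redraws + 1L
          if (redraws > 100L) stop("too many degenerate bootstrap replicates")
          next
        }
        Yb <- dataset@Y[idx, , drop = FALSE]
        bb <- qr.coef(qrX, Yb)
        # each draw of a cluster acts as a distinct cluster in the replicate
        rl <- split(seq_along(idx),
                    rep(seq_along(draw), times = lengths(rowsOf[draw])))
        seb <- clusterRobustSE(Xb, Yb, bb, rl)
        seb[seb == 0] <- .Machine$double.eps
        boot[b, , ] <- bb
        piv[b, , ] <- (bb - full$beta) / seb
        break
      }
    }
    if (redraws > 0L)
      message(sprintf("%d degenerate bootstrap replicate(s) redrawn", redraws))
  })

  qlo <- apply(piv, c(2, 3), quantile, probs = 0.025, names = FALSE)
  qhi <- apply(piv, c(2, 3), quantile, probs = 0.975, names = FALSE)
  pwLower <- full$beta - qhi * se0
  pwUpper <- full$beta - qlo * se0

  # per-term simultaneous band: max over time of the replicate deviation
  # studentized by the bootstrap SD (the max-statistic construction)
  sBoot <- apply(boot, c(2, 3), sd)
  sBoot[sBoot == 0] <- .Machine$double.eps
  dev <- abs(sweep(boot, c(2, 3), full$beta, "-"))
  dev <- sweep(dev, c(2, 3), sBoot, "/")
  qJoint <- vapply(seq_len(p), function(k)
    quantile(apply(dev[, k, , drop = FALSE], 1, max), 0.95,
             names = FALSE), numeric(1))
  jointLower <- pmin(full$beta - qJoint * sBoot, pwLower)
  jointUpper <- pmax(full$beta + qJoint * sBoot, pwUpper)
  dn <- dimnames(full$beta)
  dimnames(pwLower) <- dimnames(pwUpper) <- dn
  dimnames(jointLower) <- dimnames(jointUpper) <- dn

  new("FunctionalFit", terms = full$terms, time = dataset@time,
      beta = full$beta, pwLower = pwLower, pwUpper = pwUpper,
      jointLower = jointLower, jointUpper = jointUpper,
      boot = boot, nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Time intervals where the joint band excludes zero
#'
#' Maximal contiguous runs of timepoints at which the joint 95% band of the
#' requested term lies entirely above zero (positive intervals) or entirely
#' below zero (negative intervals). These are the intervals interpreted as
#' statistically significant after multiplicity adjustment.
#'
#' @param fit a [FunctionalFit-class].
#' @param term a term name from `fit@terms`.
#' @return data.frame with columns `start`, `end` (s) and `sign`
#'   (`"+"`/`"-"`); zero rows when the band straddles zero everywhere.
#' @export
significantIntervals <- function(fit, term) {
  if (!term %in% fit@terms)
    stop("unknown term '", term, "'; available: ",
         paste(fit@terms, collapse = ", "))
  lo <- fit@jointLower[term, ]
  hi <- fit@jointUpper[term, ]
  sgn <- ifelse(lo > 0, 1L, ifelse(hi < 0, -1L, 0L))
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep))
    return(data.frame(start = numeric(), end = numeric(), sign = character()))
  data.frame(start = fit@time[starts[keep]],
             end = fit@time[ends[keep]],
             sign = ifelse(r$values[keep] > 0, "+", "-"))
}
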