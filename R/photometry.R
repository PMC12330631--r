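#' Sum photon counts over a wavelength band
#'
#' Per-frame sum of counts over all grid wavelengths inside the closed band.
#' The published band definitions are 500-541 nm (GCaMP) and 577-618 nm
#' (tdTomato).
#'
#' @param spec a [SpectralTimeseries-class].
#' @param bandNm length-2 numeric, closed wavelength band (nm).
#' @return numeric timeseries, one value per frame.
#' @export
bandSummedSignal <- function(spec, bandNm) {
  wl <- wavelengths(spec)
  if (bandNm[1] < min(wl) || bandNm[2] > max(wl))
    stop("band lies (partly) outside the wavelength grid")
  sel <- wl >= bandNm[1] & wl <= bandNm[2]
  if (!any(sel)) stop("band contains no grid wavelengths")
  colSums(SummarizedExperiment::assay(spec, "counts")[sel, , drop = FALSE])
}

#' Spectral linear unmixing of a photometry record
#'
#' Solves, frame by frame, the least-squares decomposition of each recorded
#' emission spectrum into the reference fluorophore spectra plus (optionally)
#' a constant background component, returning one coefficient timeseries per
#' component. The default is ordinary (unconstrained) least squares; with
#' `nonNegative = TRUE` negative solutions are projected by iteratively
#' dropping negative components.
#'
#' @param spec a [SpectralTimeseries-class].
#' @param refs a [ReferenceSpectra-class] on the same wavelength grid.
#' @param background include a constant background column (default TRUE).
#' @param nonNegative constrain coefficients to be non-negative.
#' @return list with `coefficients` (components x frames matrix) and
#'   `residuals` (per-frame residual Euclidean norm).
#' @export
linearUnmix <- function(spec, refs, background = TRUE, nonNegative = FALSE) {
  wl <- wavelengths(spec)
  if (!isTRUE(all.equal(wl, refs@wavelengths)))
    stop("reference spectra are not on the record's wavelength grid")
  R <- refs@spectra
  if (background) {
    bg <- rep(1 / sqrt(nrow(R)), nrow(R))
    R <- cbind(R, background = bg)
  }
  qrR <- qr(R)
  if (qrR$rank < ncol(R))
    stop("reference matrix is rank deficient; spectra are not distinguishable")
  C <- SummarizedExperiment::assay(spec, "counts")
  coefs <- qr.coef(qrR, C)
  if (nonNegative && any(coefs < 0)) {
    for (j in which(apply(coefs < 0, 2, any))) {
      keep <- seq_len(ncol(R))
      b <- coefs[, j]
      while (any(b[keep] < -1e-12)) {
        keep <- setdiff(keep, keep[which.min(b[keep])])
        b[] <- 0
        if (length(keep))
          b[keep] <- qr.coef(qr(R[, keep, drop = FALSE]), C[, j])
      }
      coefs[, j] <- pmax(b, 0)
    }
  }
  fitted <- R %*% coefs
  res <- sqrt(colSums((C - fitted)^2))
  rownames(coefs) <- colnames(R)
  list(coefficients = coefs, residuals = res)
}

#' Remove a linear fading trend, preserving the mean
#'
#' Fits an ordinary least-squares line over the full record, subtracts it,
#' and adds back the record mean, so gradual fluorophore fading is removed
#' while the signal scale (needed for ratios and dF/F) is preserved.
#'
#' @param x numeric timeseries (>= 2 samples).
#' @return detrended series, same length and mean as `x`.
#' @export
detrendLinear <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples to fit a trend")
  t <- seq_len(n)
  fit <- lm.fit(cbind(1, t), x)
  x - fit$fitted.values + mean(x)
}

#' Downsample by non-overlapping block means
#'
#' Averages consecutive blocks of `fromHz / toHz` samples (anti-aliasing by
#' averaging rather than decimation). Used for the published 40-to-10 and
#' 20-to-10 Hz reductions.
#'
#' @param x numeric timeseries sampled at `fromHz`.
#' @param fromHz,toHz original and target rates; the ratio must be an integer.
#' @return block-mean series at `toHz`; a trailing partial block is dropped.
#' @export
downsampleMean <- function(x, fromHz, toHz) {
  r <- fromHz / toHz
  if (abs(r - round(r)) > 1e-9 || r < 1)
    stop("fromHz must be an integer multiple of toHz")
  r <- as.integer(round(r))
  nOut <- length(x) %/% r
  if (nOut * r < length(x)) x <- x[seq_len(nOut * r)]
  colMeans(matrix(x, nrow = r))
}

#' Percent dF/F of a stimulation trial
#'
#' Computes `100 * (F - Fbar) / Fbar` over a 30-s trial, where `Fbar` is the
#' mean signal over the trial's 10-s pre-stimulation period (the first
#' `preWindowS` seconds of the trial).
#'
#' @param x photon-count (or coefficient) timeseries.
#' @param rateHz sampling rate of `x`.
#' @param trialStartS trial start time (s) on the record clock (t = 0 at the
#'   first sample).
#' @param preWindowS baseline (pre-stimulation) duration at the start of the
#'   trial (s).
#' @param trialLenS total trial duration (s).
#' @return percent dF/F trace over the trial window.
#' @export
dffPerTrial <- function(x, rateHz, trialStartS, preWindowS = 10,
                        trialLenS = 30) {
  i0 <- round(trialStartS * rateHz) + 1
  i1 <- i0 + round(trialLenS * rateHz) - 1
  if (i0 < 1 || i1 > length(x)) stop("trial window exceeds the record")
  f <- x[i0:i1]
  base <- mean(f[seq_len(round(preWindowS * rateHz))])
  if (!is.finite(base) || base <= 0)
    stop("non-positive baseline mean; dF/F is undefined")
  100 * (f - base) / base
}

#' Peak stimulation-evoked response of a dF/F trace
#'
#' Maximum of the trial dF/F trace inside the response window, by default
#' 10-15 s after trial start (stimulation begins at the 10-s timepoint).
#'
#' @param dff percent dF/F trace from [dffPerTrial()] (trial-relative time).
#' @param rateHz sampling rate.
#' @param windowS closed response window (s, trial-relative).
#' @return scalar peak dF/F.
#' @export
peakResponse <- function(dff, rateHz, windowS = c(10, 15)) {
  tm <- (seq_along(dff) - 1) / rateHz
  sel <- tm >= windowS[1] & tm <= windowS[2]
  if (!any(sel)) stop("response window contains no samples")
  max(dff[sel])
}

#' Ratiometric per-trial z-scores
#'
#' Forms the element-wise ratio of the (unmixed, detrended) GCaMP and
#' tdTomato coefficient series - which cancels any multiplicative artifact
#' shared by the two fluorophores - and z-scores the ratio within each trial
#' using that trial's mean and standard deviation. Trials whose tdTomato
#' median falls below `denomFloor`, or whose ratio has zero variance, are
#' excluded with a warning.
#'
#' @param gcamp,tdtomato equal-length coefficient series (10 Hz).
#' @param trialBounds data.frame with columns `start`, `end` (s, record clock;
#'   the trial spans `[start, end)`).
#' @param rateHz sampling rate of the series.
#' @param denomFloor minimum admissible within-trial tdTomato median.
#' @return data.frame with columns `trial`, `time_s`, `z`; excluded trials are
#'   absent.
#' @export
ratioZscoreTrials <- function(gcamp, tdtomato, trialBounds, rateHz = 10,
                              denomFloor = .Machine$double.eps^0.5) {
  stopifnot(length(gcamp) == length(tdtomato))
  out <- vector("list", nrow(trialBounds))
  for (k in seq_len(nrow(trialBounds))) {
    i0 <- round(trialBounds$start[k] * rateHz) + 1
    i1 <- round(trialBounds$end[k] * rateHz)
    if (i0 < 1 || i1 > length(gcamp) || i1 <= i0) {
      warning(sprintf("trial %d outside the record; excluded", k))
      next
    }
    td <- tdtomato[i0:i1]
    if (median(td) < denomFloor) {
      warning(sprintf("trial %d: tdTomato median below floor; excluded", k))
      next
    }
    ratio <- gcamp[i0:i1] / td
    s <- sd(ratio)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("trial %d: zero-variance ratio; excluded", k))
      next
    }
    z <- (ratio - mean(ratio)) / s
    out[[k]] <- data.frame(trial = k,
                           time_s = (seq(i0, i1) - 1) / rateHz, z = z)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(trial = integer(), time_s = numeric(),
                                      z = numeric())
  rownames(res) <- NULL
  res
}

#' Average signal in the distal-delay window of each trial
#'
#' Mean z-scored signal over the 2-s window immediately preceding each Choice
#' Start event, i.e. the final ("distal") portion of the 10-s delay epoch.
#'
#' @param z numeric z-scored series at `rateHz`.
#' @param choiceStartS Choice Start times (s, record clock).
#' @param windowS window length before each event (s).
#' @param rateHz sampling rate.
#' @return numeric vector, one score per event; `NA` (with a warning) when
#'   the window falls outside the record.
#' @export
distalDelayScore <- function(z, choiceStartS, windowS = 2, rateHz = 10) {
  vapply(choiceStartS, function(cs) {
    i1 <- round(cs * rateHz)        # last sample strictly before the event
    i0 <- i1 - round(windowS * rateHz) + 1
    if (i0 < 1 || i1 > length(z)) {
      warning("distal-delay window outside the record; trial flagged NA")
      return(NA_real_)
    }
    mean(z[i0:i1])
  }, numeric(1))
}

#' Peri-event aligned average
#'
#' Extracts a fixed window around each event (event times snap to the
#' nearest sample of the 10-Hz grid) and averages across events. With
#' `normalizeUnitRange = TRUE`, each event window is first affinely mapped to
#' `[-1, +1]` (its minimum to -1, maximum to +1) before averaging, matching
#' the presentation used to compare calcium and velocity traces.
#'
#' @param z numeric series at `rateHz`.
#' @param eventS event times (s, record clock).
#' @param windowS length-2 numeric, window relative to each event (s).
#' @param rateHz sampling rate.
#' @param normalizeUnitRange scale each window to \[-1, 1\] before averaging.
#' @return list with `time` (window-relative times), `mean` (aligned average)
#'   and `n` (events used); events whose window leaves the record are skipped
#'   with a warning.
#' @export
periEventAverage <- function(z, eventS, windowS = c(-5, 5), rateHz = 10,
                             normalizeUnitRange = FALSE) {
  rel <- seq(round(windowS[1] * rateHz), round(windowS[2] * rateHz))
  acc <- NULL; n <- 0L
  for (ev in eventS) {
    c0 <- round(ev * rateHz) + 1    # snap to nearest sample
    idx <- c0 + rel
    if (idx[1] < 1 || idx[length(idx)] > length(z)) {
      warning("event window exceeds the record; event skipped")
      next
    }
    w <- z[idx]
    if (normalizeUnitRange) {
      rng <- range(w)
      if (diff(rng) == 0) w <- rep(0, length(w))
      else w <- 2 * (w - rng[1]) / diff(rng) - 1
    }
    acc <- if (is.null(acc)) w else acc + w
    n <- n + 1L
  }
  if (n == 0L) stop("no event window fits inside the record")
  list(time = rel / rateHz, mean = acc / n, n = n)
}

#' Lagged cross-correlation between calcium and velocity
#'
#' Pearson correlation at every integer lag in `[-maxLag, +maxLag]` samples
#' (default 50, i.e. +/-5 s at 10 Hz). Positive lags mean the calcium series
#' leads velocity: `r(k) = cor(ca[1:(n-k)], vel[(1+k):n])`.
#'
#' @param ca,vel equal-length series.
#' @param maxLag maximum lead/lag in samples.
#' @return data.frame with columns `lag` (samples) and `r`; `r` is `NA` if
#'   either series has zero variance.
#' @export
crosscorrLagged <- function(ca, vel, maxLag = 50L) {
  n <- length(ca)
  stopifnot(length(vel) == n)
  if (n <= maxLag + 1) stop("series shorter than the maximum lag")
  degenerate <- sd(ca) == 0 || sd(vel) == 0
  lags <- -maxLag:maxLag
  r <- vapply(lags, function(k) {
    if (degenerate) return(NA_real_)
    if (k >= 0) cor(ca[1:(n - k)], vel[(1 + k):n])
    else cor(ca[(1 - k):n], vel[1:(n + k)])
  }, numeric(1))
  data.frame(lag = lags, r = r)
}
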