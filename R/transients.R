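unscaledMad <- function(x) median(abs(x - median(x)))

# Local maxima; for flat-topped peaks the first sample of the plateau wins.
localMaxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Width at half magnitude: the reference level sits midway between the
# robust baseline and the peak; crossings are linearly interpolated. The
# search aborts (width Inf) when the signal stays above the reference for
# more than maxSamp samples or runs off the record.
peakHalfWidth <- function(x, p, ref, rateHz, maxSamp) {
  n <- length(x)
  i <- p
  while (i > 1L && x[i - 1L] > ref) {
    i <- i - 1L
    if ((p - i) > maxSamp) return(c(Inf, NA, NA))
  }
  if (i == 1L && x[1L] > ref) return(c(Inf, NA, NA))
  left <- (i - 1L) + (ref - x[i - 1L]) / (x[i] - x[i - 1L])
  i <- p
  while (i < n && x[i + 1L] > ref) {
    i <- i + 1L
    if ((i - p) > maxSamp) return(c(Inf, NA, NA))
  }
  if (i == n && x[n] > ref) return(c(Inf, NA, NA))
  right <- i + (x[i] - ref) / (x[i] - x[i + 1L])
  c((right - left) / rateHz, left, right)
}

#' Detect significant calcium transients
#'
#' Peak detection on a calcium signal. A local maximum is a significant
#' event when its magnitude - its height above the robust baseline, taken as
#' the series median - reaches `madMultiplier x MAD` of the analyzed series
#' (MAD unscaled: the default multiplier 2.91 already folds in the Gaussian
#' consistency factor, approximating the two-sided 95% band of Gaussian
#' noise). Peaks closer than the minimum separation are resolved by keeping
#' the taller; widths are measured at half magnitude (the level midway
#' between baseline and peak, crossings linearly interpolated) and must lie
#' inside `[minWidthS, maxWidthS]` - the width band is what rejects
#' single-sample shot-noise excursions. Referencing magnitude to the
#' baseline rather than to topographic saddles keeps the false-event rate on
#' pure noise very low, since an above-threshold noise sample is essentially
#' never flanked by the sustained elevation the minimum width demands.
#'
#' @param x numeric calcium series (typically 10-Hz percent dF/F or z-scores).
#' @param params a [TransientParams-class].
#' @param rateHz sampling rate of `x`.
#' @return data.frame with one row per event: `peak_time_s`, `magnitude`,
#'   `half_width_s`. A constant series yields zero events.
#' @export
detectTransients <- function(x, params = transientParams(), rateHz = 10) {
  n <- length(x)
  if (n <= round(params@featureWindowS * rateHz))
    stop("series shorter than the feature window")
  empty <- data.frame(peak_time_s = numeric(), magnitude = numeric(),
                      half_width_s = numeric())
  m <- unscaledMad(x)
  if (m == 0) return(empty)
  base <- median(x)
  peaks <- localMaxima(x)
  if (!length(peaks)) return(empty)

  # minimum separation: keep the taller of any pair closer than the limit
  ord <- order(x[peaks], decreasing = TRUE)
  keep <- logical(length(peaks))
  minSep <- params@minSeparationS * rateHz
  for (j in ord) {
    if (any(keep & abs(peaks - peaks[j]) < minSep)) next
    keep[j] <- TRUE
  }
  peaks <- peaks[keep]

  mag <- x[peaks] - base
  sig <- mag >= params@madMultiplier * m
  peaks <- peaks[sig]; mag <- mag[sig]
  if (!length(peaks)) return(empty)

  maxSamp <- ceiling(params@maxWidthS * rateHz) + 1L
  wlr <- vapply(seq_along(peaks), function(j)
    peakHalfWidth(x, peaks[j], base + mag[j] / 2, rateHz, maxSamp),
    numeric(3))
  widths <- wlr[1, ]
  ok <- widths >= params@minWidthS & widths <= params@maxWidthS
  peaks <- peaks[ok]; mag <- mag[ok]; widths <- widths[ok]
  wlr <- wlr[, ok, drop = FALSE]
  if (!length(peaks)) return(empty)

  # peaks whose half-magnitude supports overlap are one contiguous
  # elevation (e.g. the decay shoulder of a compound event): keep the taller
  ord <- order(mag, decreasing = TRUE)
  keep <- logical(length(peaks))
  for (j in ord) {
    clash <- keep & pmax(wlr[2, ], wlr[2, j]) <= pmin(wlr[3, ], wlr[3, j])
    if (!any(clash)) keep[j] <- TRUE
  }
  peaks <- peaks[keep]; mag <- mag[keep]; widths <- widths[keep]
  if (!length(peaks)) return(empty)

  o <- order(peaks)
  data.frame(peak_time_s = (peaks[o] - 1) / rateHz,
             magnitude = mag[o],
             half_width_s = widths[o])
}

#' Binned spontaneous-event statistics, optionally Day-1 normalized
#'
#' Splits a baseline record (canonically 10 min) into consecutive bins
#' (default 2.5 min), runs [detectTransients()] per bin, averages the event
#' magnitude, frequency (events/s) and half-width across bins, and divides
#' by a reference day's values when one is supplied (the published analyses
#' normalize to the first input-output day).
#'
#' @param x baseline calcium series.
#' @param params a [TransientParams-class].
#' @param rateHz sampling rate.
#' @param binLenS bin length (s).
#' @param day1Reference optional list with `magnitude`, `frequency`,
#'   `half_width` from the reference day (un-normalized).
#' @return list with `magnitude`, `frequency`, `half_width` (bin-averaged,
#'   normalized if a reference is given) and `perBin` (data.frame of raw
#'   per-bin values).
#' @export
spontaneousStats <- function(x, params = transientParams(), rateHz = 10,
                             binLenS = 150, day1Reference = NULL) {
  binLen <- round(binLenS * rateHz)
  nBins <- length(x) %/% binLen
  if (nBins < 1) stop("record shorter than one bin")
  perBin <- do.call(rbind, lapply(seq_len(nBins), function(b) {
    seg <- x[((b - 1) * binLen + 1):(b * binLen)]
    ev <- detectTransients(seg, params, rateHz)
    data.frame(bin = b, n_events = nrow(ev),
               magnitude = if (nrow(ev)) mean(ev$magnitude) else NA_real_,
               frequency = nrow(ev) / binLenS,
               half_width = if (nrow(ev)) mean(ev$half_width_s) else NA_real_)
  }))
  res <- list(magnitude = mean(perBin$magnitude, na.rm = TRUE),
              frequency = mean(perBin$frequency),
              half_width = mean(perBin$half_width, na.rm = TRUE),
              perBin = perBin)
  if (!is.null(day1Reference)) {
    for (f in c("magnitude", "frequency", "half_width")) {
      if (!is.finite(day1Reference[[f]]) || day1Reference[[f]] == 0)
        stop("zero or missing reference value for ", f)
      res[[f]] <- res[[f]] / day1Reference[[f]]
    }
  }
  res
}
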