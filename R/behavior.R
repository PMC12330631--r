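#' Daily accuracy of a training record
#'
#' Fraction of correct trials per training day. A training record is a
#' data.frame with one row per trial and columns `mouse_id`, `day`, `trial`
#' and `outcome` (0 = correct, 1 = incorrect, matching the regression
#' coding), plus any group labels.
#'
#' @param record training-record data.frame.
#' @return data.frame with columns `mouse_id`, `day`, `n_trials`, `accuracy`.
#' @export
accuracyByDay <- function(record) {
  stopifnot(all(c("mouse_id", "day", "outcome") %in% names(record)))
  if (!nrow(record)) stop("empty training record")
  out <- do.call(rbind, lapply(
    split(record, list(record$mouse_id, record$day), drop = TRUE),
    function(d) data.frame(mouse_id = d$mouse_id[1], day = d$day[1],
                           n_trials = nrow(d),
                           accuracy = mean(d$outcome == 0))))
  out <- out[order(out$mouse_id, out$day), ]
  rownames(out) <- NULL
  out
}

#' Days to reach the learning criterion
#'
#' The criterion is three consecutive days at or above 70% correct; training
#' is capped at 15 days. Returns the (1-based) day on which the run of
#' qualifying days is completed - a mouse at criterion from day 1 scores 3 -
#' or the cap with `reached = FALSE` when the criterion is never met.
#'
#' @param accuracies per-day accuracy vector for one mouse (fractions in \[0, 1\]).
#' @param threshold accuracy criterion.
#' @param consecutive required run length of qualifying days.
#' @param maxDays training cap (days).
#' @return list with `days` (integer) and `reached` (logical).
#' @examples
#' daysToCriterion(c(0.6, 0.7, 0.7, 0.7))  # day 4, reached
#' @export
daysToCriterion <- function(accuracies, threshold = 0.70, consecutive = 3L,
                            maxDays = 15L) {
  if (length(accuracies) > maxDays)
    stop("more accuracy values than the training cap allows")
  ok <- accuracies >= threshold
  run <- 0L
  for (d in seq_along(ok)) {
    run <- if (ok[d]) run + 1L else 0L
    if (run >= consecutive) return(list(days = d, reached = TRUE))
  }
  list(days = as.integer(maxDays), reached = FALSE)
}

#' Early/late split of a mouse's trials
#'
#' Partitions `n` trials by index into the first third ("early") and final
#' third ("late"), each of size `floor(n / 3)`.
#'
#' @param n number of trials for the mouse (>= 3).
#' @return list with integer index vectors `early` and `late`.
#' @examples
#' earlyLateSplit(9)   # early 1:3, late 7:9
#' earlyLateSplit(4)   # early 1,  late 4
#' @export
earlyLateSplit <- function(n) {
  if (n < 3) stop("need at least 3 trials to form thirds; mouse excluded")
  k <- floor(n / 3)
  list(early = seq_len(k), late = seq.int(n - k + 1L, n))
}

#' Correlate per-mouse distal-delay scores with training accuracy
#'
#' Pearson correlation between paired per-mouse values, typically the mean
#' distal-delay calcium score in early training against overall training
#' accuracy.
#'
#' @param scores,accuracy equal-length numeric vectors, one value per mouse.
#' @return list with `r`, `r2`, `slope` (least-squares slope of accuracy on
#'   score), and `n`; `r` is `NA` with a warning when either input has zero
#'   variance.
#' @export
correlateWithAccuracy <- function(scores, accuracy) {
  stopifnot(length(scores) == length(accuracy))
  ok <- is.finite(scores) & is.finite(accuracy)
  scores <- scores[ok]; accuracy <- accuracy[ok]
  n <- length(scores)
  if (n < 3) stop("need at least 3 paired values")
  if (sd(scores) == 0 || sd(accuracy) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, r2 = NA_real_, slope = NA_real_, n = n))
  }
  r <- cor(scores, accuracy)
  list(r = r, r2 = r^2,
       slope = cov(scores, accuracy) / var(scores), n = n)
}
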