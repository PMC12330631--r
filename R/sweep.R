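#' Sweep the vHPC-to-VIP synaptic weight and summarize evoked peaks
#'
#' Systematically decreases the vHPC-to-VIP weight from its baseline (1.6)
#' over a descending grid (default six evenly spaced values down to 0.85).
#' For each weight, `nSims` independent simulations are run, each the average
#' of `runsPerSim` runs, and the baseline-subtracted evoked peak of every
#' cell class is recorded. Per-run seeds are derived from the master seed so
#' the whole sweep is reproducible and runs are mutually independent.
#'
#' @param config base [NetworkConfig-class]; its vHPC-to-VIP entry is replaced
#'   by each grid value in turn.
#' @param weightValues descending weight grid.
#' @param nSims simulations per weight (>= 2 so a SEM exists).
#' @param runsPerSim runs averaged per simulation.
#' @param seed master seed.
#' @param baselineWindow,responseWindow windows passed to [evokedPeak()].
#' @return a [SweepResult-class]; see [sweepSummary()] and
#'   [monotonicitySummary()].
#' @export
runWeightSweep <- function(config,
                           weightValues = c(1.6, 1.45, 1.3, 1.15, 1.0, 0.85),
                           nSims = 10L, runsPerSim = 5L, seed = 1L,
                           baselineWindow = c(0.1, 2),
                           responseWindow = c(2, 10)) {
  if (nSims < 2L) stop("nSims must be >= 2 so the SEM is defined")
  if (any(weightValues < 0) ||
      any(weightValues > config@weights["vHPC", "VIP"] + 1e-12))
    stop("weight values must lie in [0, baseline vHPC->VIP weight]")
  nW <- length(weightValues)
  simSeeds <- withSeed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, nW * nSims), nW, nSims))
  rows <- vector("list", nW * nSims)
  k <- 0L
  for (wi in seq_len(nW)) {
    cfg <- config
    cfg@weights["vHPC", "VIP"] <- weightValues[wi]
    for (si in seq_len(nSims)) {
      tr <- simulateCondition(cfg, nRuns = runsPerSim, seed = simSeeds[wi, si])
      pk <- vapply(CELL_CLASSES, function(x)
        evokedPeak(tr@activity[x, ], tr@time, baselineWindow, responseWindow),
        numeric(1))
      k <- k + 1L
      rows[[k]] <- data.frame(weight = weightValues[wi], class = CELL_CLASSES,
                              sim = si, peak = unname(pk))
    }
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  new("SweepResult", peaks = peaks, weights = weightValues,
      nSims = as.integer(nSims), runsPerSim = as.integer(runsPerSim),
      seed = as.integer(seed), configHash = configHash(config))
}

#' Directional summary of a weight sweep
#'
#' For each cell class, the Spearman rank correlation between the swept
#' weight value and the mean evoked peak, the implied direction, and whether
#' that direction matches the expected disinhibitory-circuit pattern:
#' weakening the vHPC-to-VIP weight reduces evoked VIP, PV and pyramidal
#' activity (positive correlation with the weight) and enhances evoked SST
#' activity (negative correlation).
#'
#' @param sweep a [SweepResult-class] with at least 3 weight values.
#' @return data.frame with columns `class`, `rho`, `direction`
#'   (`"+"`, `"-"` or `NA` when all means tie), `expected`, `consistent`.
#' @export
monotonicitySummary <- function(sweep) {
  if (length(sweep@weights) < 3L)
    stop("need at least 3 weight values for a rank correlation")
  expected <- c(VIP = 1, SST = -1, PV = 1, PYR = 1)
  sm <- sweepSummary(sweep)
  out <- lapply(CELL_CLASSES, function(x) {
    d <- sm[sm$class == x, ]
    rho <- if (length(unique(d$mean)) == 1L) NA_real_
      else suppressWarnings(cor(d$weight, d$mean, method = "spearman"))
    dir <- if (is.na(rho) || rho == 0) NA_character_
      else if (rho > 0) "+" else "-"
    data.frame(class = x, rho = rho, direction = dir,
               expected = ifelse(expected[x] > 0, "+", "-"),
               consistent = if (is.na(rho)) NA else
                 sign(rho) == expected[x])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
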