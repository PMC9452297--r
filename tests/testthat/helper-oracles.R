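## Independent brute-force oracles used to freeze expected values. These are
## deliberately written with different mechanics (explicit frame scans,
## double loops) than the package implementations they check.

## Literal run enumeration: scan frames, collect maximal runs where above[] is
## TRUE, as (start, end) pairs.
enumRunsOracle <- function(above) {
  n <- length(above)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  runs
}

## Exhaustive transient detector: enumerate every run at every threshold and
## apply the significance, merge and minimum-duration rules literally.
oracleDetectTransients <- function(x, thresholds = seq(1, 4, by = 0.2),
                                   fprMax = 0.001) {
  z <- (x - median(x)) / sd(x)
  n <- length(z)
  sig <- rep(FALSE, n)
  for (t in thresholds) {
    posRuns <- enumRunsOracle(z > t)
    negRuns <- enumRunsOracle(z < -t)
    posLens <- vapply(posRuns, function(r) r[2] - r[1] + 1L, numeric(1))
    negLens <- vapply(negRuns, function(r) r[2] - r[1] + 1L, numeric(1))
    for (r in posRuns) {
      len <- r[2] - r[1] + 1L
      fpr <- sum(negLens >= len) / sum(posLens >= len)
      if (fpr < fprMax) sig[r[1]:r[2]] <- TRUE
    }
  }
  runs <- enumRunsOracle(sig)
  if (length(runs) > 1) {
    for (k in seq_len(length(runs) - 1L)) {
      gap <- runs[[k + 1L]][1] - runs[[k]][2] - 1L
      if (gap < 2L) sig[runs[[k]][2]:runs[[k + 1L]][1]] <- TRUE
    }
  }
  for (r in enumRunsOracle(sig)) {
    if (r[2] - r[1] + 1L < 2L) sig[r[1]:r[2]] <- FALSE
  }
  out <- x
  out[!sig] <- 0
  list(mask = sig, dff = out)
}

## Direct sliding-window percentile baseline, frame by frame.
oracleDffBaseline <- function(raw, frameRate, windowS = 60, prob = 0.3) {
  n <- length(raw)
  half <- round(windowS * frameRate) %/% 2
  vapply(seq_len(n), function(i)
    quantile(raw[max(1, i - half):min(n, i + half)], prob, names = FALSE),
    numeric(1))
}

## Direct per-frame accumulation of binned activity means.
oracleBinMeans <- function(act, pos, spd, tid, trialsUse, thr, nBins,
                           trackLength) {
  binSize <- trackLength / nBins
  sums <- matrix(0, nrow(act), nBins)
  counts <- numeric(nBins)
  for (f in seq_along(pos)) {
    if (!(tid[f] %in% trialsUse) || spd[f] <= thr) next
    b <- min(floor(pos[f] / binSize), nBins - 1) + 1
    sums[, b] <- sums[, b] + act[, f]
    counts[b] <- counts[b] + 1
  }
  means <- sweep(sums, 2, pmax(counts, 1), "/")
  means[, counts == 0] <- NA_real_
  list(mean = means, occupancy = counts / sum(counts))
}

## Construct a minimal annotated session from explicit behaviour streams.
toySession <- function(position, speed = rep(20, length(position)),
                       frameRate = 30, trackLength = 200,
                       rewardZone = c(100, 120), licks = NULL,
                       rewards = NULL, trialTypes = NULL, dff = NULL) {
  wrap <- c(FALSE, diff(position) < -trackLength / 2)
  tid <- cumsum(wrap) + 1L
  if (is.null(licks))
    licks <- data.frame(frame = integer(0), kind = character(0),
                        trial = integer(0), position = numeric(0))
  if (is.null(rewards))
    rewards <- data.frame(frame = integer(0), volume = numeric(0),
                          manual = logical(0), trial = integer(0))
  x <- CalciumSession(position = position, speed = speed, trialId = tid,
                      frameRate = frameRate, trackLength = trackLength,
                      rewardZone = rewardZone, dff = dff, licks = licks,
                      rewards = rewards)
  annotateTrials(x, trialTypes = trialTypes)
}

## A lap trajectory visiting all bins at constant speed: nFramesPerLap frames
## per lap, repeated nLaps times.
lapPosition <- function(nLaps, nFramesPerLap, trackLength = 200) {
  rep(seq(0, trackLength - trackLength / nFramesPerLap,
          length.out = nFramesPerLap), nLaps)
}

## Pair-counting agreement between two partitions (adjusted Rand index).
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  (sumij - expected) / ((sumi + sumj) / 2 - expected)
}
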