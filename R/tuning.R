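## Spatial tuning: binned activity, circular Gaussian smoothing, the
## block-permutation behavioural shuffle null, place-field calling, spatial
## information, and per-field properties.

#' @noRd
.frameBins <- function(session, trialsUse, runThresholdCmS, nBins) {
  pos <- position(session)
  binSize <- trackLength(session) / nBins
  bin <- pmin(floor(pos / binSize), nBins - 1L)
  keep <- trialId(session) %in% trialsUse & speed(session) > runThresholdCmS
  bin[!keep] <- NA_integer_
  bin
}

#' Mean activity per bin for an activity matrix given per-frame bins
#' @param act cells x frames; bin per-frame 0-based bin or NA (excluded).
#' @return list(mean = cells x bins, counts = per-bin frame counts)
#' @noRd
.binMeans <- function(act, bin, nBins) {
  sel <- which(!is.na(bin))
  ind <- matrix(0, length(sel), nBins)
  ind[cbind(seq_along(sel), bin[sel] + 1L)] <- 1
  sums <- act[, sel, drop = FALSE] %*% ind
  counts <- colSums(ind)
  means <- sweep(sums, 2, pmax(counts, 1), "/")
  means[, counts == 0] <- NA_real_
  list(mean = means, counts = counts)
}

#' Spatially bin activity over running frames of selected trials
#'
#' Only frames belonging to `trialsUse` with speed above `runThresholdCmS`
#' contribute. The track is divided into `nBins` equal bins; activity is
#' averaged per bin per trial (NA where the bin was not visited on the trial)
#' and over all contributing frames for the session mean. Occupancy is the
#' fraction of contributing frames per bin.
#'
#' @param session a [CalciumSession-class].
#' @param activity cells x frames matrix; defaults to the significant
#'   transient traces.
#' @param trialsUse trial ids to include; defaults to the eligible trials.
#' @param runThresholdCmS running-speed threshold in cm/s.
#' @param nBins number of spatial bins.
#' @return list with `perTrial` (trials x bins x cells array), `mean`
#'   (cells x bins), `occupancy` (length nBins, sums to 1), `counts`.
#' @export
binActivity <- function(session, activity = NULL,
                        trialsUse = eligibleTrials(session),
                        runThresholdCmS = 5, nBins = 40) {
  stopifnot(is(session, "CalciumSession"))
  if (is.null(activity)) activity <- transientTraces(session)
  bin <- .frameBins(session, trialsUse, runThresholdCmS, nBins)
  if (all(is.na(bin)))
    stop("no running frames in any selected trial")
  bm <- .binMeans(activity, bin, nBins)
  tid <- trialId(session)
  nCells <- nrow(activity)
  perTrial <- array(NA_real_, c(length(trialsUse), nBins, nCells))
  for (k in seq_along(trialsUse)) {
    b <- bin
    b[tid != trialsUse[k]] <- NA_integer_
    if (all(is.na(b))) next
    perTrial[k, , ] <- t(.binMeans(activity, b, nBins)$mean)
  }
  list(perTrial = perTrial, mean = bm$mean,
       occupancy = bm$counts / sum(bm$counts), counts = bm$counts,
       trialsUse = trialsUse)
}

#' Circular Gaussian smoothing of binned tuning
#'
#' Convolution with a unit-sum Gaussian kernel (s.d. `sigmaBins` bins) with
#' circular padding. Missing bins are bridged: weights are renormalized over
#' the non-missing neighbours, and a bin with no non-missing neighbour mass
#' stays NA.
#'
#' @param x numeric vector over bins, or a cells x bins matrix.
#' @param sigmaBins kernel standard deviation in bins.
#' @return smoothed object of the same shape.
#' @export
smoothCircular <- function(x, sigmaBins = 1) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else x
  n <- ncol(m)
  k <- .circGaussKernel(n, sigmaBins)
  ## K[j, i] = weight of source bin j for target bin i
  K <- sapply(0:(n - 1), function(i) k[((0:(n - 1)) - i) %% n + 1])
  w <- !is.na(m)
  m0 <- m
  m0[!w] <- 0
  num <- m0 %*% K
  den <- (w + 0) %*% K
  out <- num / den
  out[den == 0] <- NA_real_
  if (vec) as.numeric(out) else out
}

#' Deterministic block-shuffle frame index
#'
#' The behaviour stream of `n` frames is circularly shifted by `offset`
#' frames, cut into `nBlocks` contiguous blocks of near-equal length (frame
#' counts differ by at most one; the remainder goes to the leading blocks),
#' and the blocks are rearranged in `blockOrder`. Returns the index vector
#' `idx` such that the shuffled behaviour is `behaviour[idx]`.
#'
#' @param n number of frames.
#' @param offset circular shift in frames (0..n-1).
#' @param blockOrder permutation of `seq_len(nBlocks)`.
#' @param nBlocks number of blocks.
#' @return integer index vector of length n.
#' @export
blockShuffleIndex <- function(n, offset, blockOrder, nBlocks = 6) {
  if (n < nBlocks) stop("fewer frames than blocks")
  stopifnot(length(blockOrder) == nBlocks,
            all(sort(blockOrder) == seq_len(nBlocks)))
  shifted <- ((seq_len(n) - 1 + offset) %% n) + 1
  base <- n %/% nBlocks
  sizes <- rep(base, nBlocks)
  extra <- n %% nBlocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  unlist(lapply(blockOrder, function(b) shifted[starts[b]:ends[b]]),
         use.names = FALSE)
}

#' Block-permutation shuffle null for spatial tuning
#'
#' On each shuffle the behaviour streams (spatial bin, running mask, trial
#' eligibility) are circularly shifted by a uniform random frame offset, cut
#' into `nBlocks` near-equal contiguous blocks, and the block order is
#' permuted uniformly, while the neural traces stay fixed. This perturbs the
#' activity-position pairing while preserving the autocorrelation of both.
#' Binned (and smoothed) tuning is recomputed per shuffle.
#'
#' @inheritParams binActivity
#' @param nShuffles number of shuffles.
#' @param seed RNG seed.
#' @param sigmaBins smoothing kernel s.d.
#' @param nBlocks number of blocks.
#' @return list with `nullCurve` (cells x bins elementwise 99th percentile of
#'   the smoothed shuffle curves), `shuffleH` (cells x nShuffles spatial
#'   information values), `shuffleSmoothed` (cells x bins x nShuffles array).
#' @export
shuffleNull <- function(session, activity = NULL,
                        trialsUse = eligibleTrials(session),
                        nShuffles = 1000, seed = 1, runThresholdCmS = 5,
                        nBins = 40, sigmaBins = 1, nBlocks = 6,
                        probs = 0.99) {
  stopifnot(is(session, "CalciumSession"))
  if (is.null(activity)) activity <- transientTraces(session)
  bin <- .frameBins(session, trialsUse, runThresholdCmS, nBins)
  n <- length(bin)
  if (n < nBlocks) stop("fewer frames than blocks")
  set.seed(seed)
  nCells <- nrow(activity)
  curves <- array(NA_real_, c(nCells, nBins, nShuffles))
  shuffleH <- matrix(NA_real_, nCells, nShuffles)
  for (s in seq_len(nShuffles)) {
    idx <- blockShuffleIndex(n, sample.int(n, 1) - 1L,
                             sample.int(nBlocks), nBlocks)
    sbin <- bin[idx]
    bm <- .binMeans(activity, sbin, nBins)
    occ <- bm$counts / sum(bm$counts)
    curves[, , s] <- smoothCircular(bm$mean, sigmaBins)
    shuffleH[, s] <- apply(bm$mean, 1, spatialInformation, occupancy = occ)
  }
  nullCurve <- apply(curves, c(1, 2), quantile, probs = probs,
                     na.rm = TRUE, names = FALSE)
  list(nullCurve = nullCurve, shuffleH = shuffleH,
       shuffleSmoothed = curves)
}

#' Detect place fields against a shuffle null
#'
#' Significant bins are those where the smoothed tuning strictly exceeds the
#' null curve; fields are maximal circular runs of at least `minRunBins`
#' significant bins (bin n-1 is adjacent to bin 0). A cell with at least one
#' field is a place cell.
#'
#' @param smoothed cells x bins smoothed tuning (or a vector for one cell).
#' @param nullCurve matching 99th-percentile shuffle curve.
#' @param minRunBins minimum field extent in bins.
#' @param binSizeCm bin width in cm (for field widths).
#' @return list with `fields` (data.frame cell, start_bin, n_bins, peak_bin,
#'   width_cm) and `placeCell` (per-cell logical).
#' @export
detectPlaceFields <- function(smoothed, nullCurve, minRunBins = 3,
                              binSizeCm = 5) {
  if (is.null(dim(smoothed))) smoothed <- matrix(smoothed, nrow = 1)
  if (is.null(dim(nullCurve))) nullCurve <- matrix(nullCurve, nrow = 1)
  stopifnot(dim(smoothed) == dim(nullCurve))
  nBins <- ncol(smoothed)
  rows <- list()
  placeCell <- logical(nrow(smoothed))
  for (i in seq_len(nrow(smoothed))) {
    sig <- !is.na(smoothed[i, ]) & !is.na(nullCurve[i, ]) &
      smoothed[i, ] > nullCurve[i, ]
    runs <- .circularRuns(sig)
    runs <- runs[runs$length >= minRunBins, , drop = FALSE]
    if (nrow(runs)) {
      placeCell[i] <- TRUE
      for (k in seq_len(nrow(runs))) {
        bins <- (runs$start[k] + 0:(runs$length[k] - 1)) %% nBins
        peak <- bins[which.max(smoothed[i, bins + 1])]
        rows[[length(rows) + 1L]] <- data.frame(
          cell = i, start_bin = runs$start[k], n_bins = runs$length[k],
          peak_bin = peak, width_cm = runs$length[k] * binSizeCm)
      }
    }
  }
  fields <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(0), start_bin = integer(0), n_bins = integer(0),
               peak_bin = integer(0), width_cm = numeric(0))
  list(fields = fields, placeCell = placeCell)
}

#' Spatial information of a binned tuning curve
#'
#' \deqn{H = \sum_i p_i a_i \log_2(a_i / a)}
#' where \eqn{p_i} is the occupancy fraction of bin i, \eqn{a_i} the mean
#' activity there and \eqn{a = \sum_i p_i a_i} the overall mean. Terms with
#' \eqn{a_i = 0} contribute 0; a silent cell (a = 0) has H = 0.
#'
#' @param activity per-bin mean activity (NA bins are ignored).
#' @param occupancy per-bin occupancy fractions.
#' @return spatial information in bits.
#' @export
spatialInformation <- function(activity, occupancy) {
  ok <- !is.na(activity) & !is.na(occupancy) & occupancy > 0
  a_i <- activity[ok]
  p_i <- occupancy[ok] / sum(occupancy[ok])
  if (any(a_i < 0)) stop("activity must be nonnegative")
  a <- sum(p_i * a_i)
  if (a == 0) return(0)
  nz <- a_i > 0
  sum(p_i[nz] * a_i[nz] * log2(a_i[nz] / a))
}

#' Full spatial-tuning analysis of a session
#'
#' Bins the significant-transient activity over running frames of eligible
#' trials, smooths with a circular Gaussian kernel, builds the
#' block-permutation shuffle null, calls place fields against its 99th
#' percentile, and computes spatial information and its shuffle-mean
#' normalization for every cell.
#'
#' @inheritParams shuffleNull
#' @param smoothedForH use smoothed rather than raw binned activity in the
#'   spatial-information formula.
#' @return a [SpatialTuningSet-class].
#' @export
computeSpatialTuning <- function(session, activity = NULL,
                                 trialsUse = eligibleTrials(session),
                                 nShuffles = 1000, seed = 1,
                                 runThresholdCmS = 5, nBins = 40,
                                 sigmaBins = 1, nBlocks = 6,
                                 smoothedForH = FALSE) {
  stopifnot(is(session, "CalciumSession"))
  if (is.null(activity)) activity <- transientTraces(session)
  ba <- binActivity(session, activity, trialsUse, runThresholdCmS, nBins)
  smoothed <- smoothCircular(ba$mean, sigmaBins)
  null <- shuffleNull(session, activity, trialsUse, nShuffles, seed,
                      runThresholdCmS, nBins, sigmaBins, nBlocks)
  pf <- detectPlaceFields(smoothed, null$nullCurve, minRunBins = 3,
                          binSizeCm = trackLength(session) / nBins)
  base <- if (smoothedForH) smoothed else ba$mean
  H <- apply(base, 1, spatialInformation, occupancy = ba$occupancy)
  shuffleHMean <- rowMeans(null$shuffleH, na.rm = TRUE)
  Hnorm <- ifelse(shuffleHMean > 0, H / shuffleHMean, NA_real_)
  new("SpatialTuningSet", occupancy = ba$occupancy, perTrial = ba$perTrial,
      meanActivity = ba$mean, smoothed = smoothed,
      nullCurve = null$nullCurve, H = H, Hnorm = Hnorm,
      shuffleHMean = shuffleHMean, fields = pf$fields,
      placeCell = pf$placeCell, eligibleTrials = as.integer(trialsUse),
      params = list(nShuffles = nShuffles, seed = seed,
                    runThresholdCmS = runThresholdCmS, sigmaBins = sigmaBins,
                    nBlocks = nBlocks, smoothedForH = smoothedForH))
}

#' Per-field properties of a place cell
#'
#' Trial-to-trial correlation (mean off-diagonal of the trial x trial Pearson
#' correlation matrix of the cell's trial-wise binned activity, with pairs
#' where either trial lacked activity set to 0), the fraction of eligible
#' trials with at least one significant transient inside any of the cell's
#' fields, spatial selectivity ((in-field - out-of-field) / (in-field +
#' out-of-field) mean binned activity), and total field width.
#'
#' @param tuning a [SpatialTuningSet-class].
#' @param session the session it was computed from.
#' @param cell cell index.
#' @param activity activity matrix used for `fractionActive` (defaults to the
#'   significant transient traces).
#' @return list(trialToTrialCorr, fractionActive, selectivity, widthCm).
#' @export
fieldProperties <- function(tuning, session, cell, activity = NULL) {
  stopifnot(is(tuning, "SpatialTuningSet"))
  if (!tuning@placeCell[cell]) stop("cell has no place field")
  if (is.null(activity)) activity <- transientTraces(session)
  trialsUse <- tuning@eligibleTrials
  if (length(trialsUse) < 2) stop("need at least 2 eligible trials")
  perTrial <- tuning@perTrial[, , cell, drop = TRUE]
  nTrial <- nrow(perTrial)

  hasAct <- apply(perTrial, 1, function(r) any(!is.na(r) & r > 0))
  cc <- matrix(0, nTrial, nTrial)
  for (i in seq_len(nTrial - 1)) for (j in (i + 1):nTrial) {
    if (hasAct[i] && hasAct[j]) {
      ok <- !is.na(perTrial[i, ]) & !is.na(perTrial[j, ])
      r <- if (sum(ok) >= 2 && sd(perTrial[i, ok]) > 0 &&
               sd(perTrial[j, ok]) > 0)
        cor(perTrial[i, ok], perTrial[j, ok]) else 0
      cc[i, j] <- cc[j, i] <- r
    }
  }
  trialCorr <- mean(cc[upper.tri(cc)])

  flds <- tuning@fields[tuning@fields$cell == cell, , drop = FALSE]
  nBins <- ncol(tuning@meanActivity)
  fieldBins <- unique(unlist(lapply(seq_len(nrow(flds)), function(k)
    (flds$start_bin[k] + 0:(flds$n_bins[k] - 1)) %% nBins))) + 1L

  bin <- .frameBins(session, trialsUse, tuning@params$runThresholdCmS, nBins)
  tid <- trialId(session)
  active <- vapply(trialsUse, function(t) {
    sel <- which(tid == t & !is.na(bin) & (bin + 1L) %in% fieldBins)
    length(sel) > 0 && any(activity[cell, sel] > 0)
  }, logical(1))
  fractionActive <- mean(active)

  m <- tuning@meanActivity[cell, ]
  inF <- mean(m[fieldBins], na.rm = TRUE)
  outF <- mean(m[-fieldBins], na.rm = TRUE)
  selectivity <- if (inF + outF > 0) (inF - outF) / (inF + outF) else
    NA_real_

  list(trialToTrialCorr = trialCorr, fractionActive = fractionActive,
       selectivity = selectivity, widthCm = sum(flds$width_cm))
}
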