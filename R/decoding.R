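## Poisson naive-Bayes position decoding on the circular track, group
## comparisons with size matching, and the activity-matching subsampler.

#' Split eligible trials into training (even) and testing (odd) halves
#'
#' Trial numbering is 1-based over the eligible trials in session order, so
#' the first eligible trial is odd (testing) and the second is even
#' (training).
#'
#' @param trialsUse eligible trial ids in session order.
#' @return list(train, test).
#' @export
trainTestSplit <- function(trialsUse) {
  k <- seq_along(trialsUse)
  list(train = trialsUse[k %% 2 == 0], test = trialsUse[k %% 2 == 1])
}

#' Fit decoder templates from training trials
#'
#' The template of a cell is its mean binned activity over the running frames
#' of the training (even-numbered eligible) trials, floored at
#' `epsilonFrac` times the population-mean nonzero template value to keep
#' logarithms finite. Bins never visited in training are excluded from the
#' posterior support.
#'
#' @param session a [CalciumSession-class].
#' @param activity cells x frames activity (defaults to significant
#'   transient traces).
#' @param trainTrials training trial ids (defaults to the even-numbered
#'   eligible trials).
#' @param runThresholdCmS running-speed threshold.
#' @param nBins number of spatial bins.
#' @param epsilonFrac template floor as a fraction of the mean nonzero value.
#' @return a [TemplateSet-class].
#' @export
fitTemplates <- function(session, activity = NULL, trainTrials = NULL,
                         runThresholdCmS = 5, nBins = 40,
                         epsilonFrac = 0.01) {
  stopifnot(is(session, "CalciumSession"))
  if (is.null(activity)) activity <- transientTraces(session)
  if (is.null(trainTrials)) trainTrials <- trainTestSplit(
    eligibleTrials(session))$train
  if (!length(trainTrials)) stop("no training trials")
  ba <- binActivity(session, activity, trainTrials, runThresholdCmS, nBins)
  tmpl <- ba$mean
  validBins <- ba$counts > 0
  nz <- tmpl[!is.na(tmpl) & tmpl > 0]
  eps <- if (length(nz)) epsilonFrac * mean(nz) else epsilonFrac
  tmpl[, validBins] <- pmax(tmpl[, validBins, drop = FALSE], eps)
  new("TemplateSet", templates = tmpl, tau = 1 / frameRate(session),
      epsilon = eps, trainTrials = as.integer(trainTrials),
      validBins = validBins)
}

#' Decode one frame of population activity
#'
#' Log-posterior over position bins under the Poisson naive-Bayes model with
#' uniform prior:
#' \deqn{\log P(pos \mid a) = \sum_i a_i \log f_i(pos) - \tau \sum_i f_i(pos)
#'       + const}
#' normalized by log-sum-exp. The decoded bin is the argmax; ties go to the
#' lowest bin index.
#'
#' @param templates a [TemplateSet-class].
#' @param a nonnegative per-cell activity on the frame.
#' @return list(posterior, decodedBin) with the posterior summing to 1 over
#'   valid bins (0-based decodedBin).
#' @export
decodeFrame <- function(templates, a) {
  stopifnot(is(templates, "TemplateSet"), all(a >= 0),
            length(a) == nrow(templates@templates))
  valid <- templates@validBins
  if (!any(valid)) stop("no valid template bins")
  f <- templates@templates[, valid, drop = FALSE]
  lp <- as.numeric(crossprod(a, log(f)) - templates@tau * colSums(f))
  post <- rep(0, length(valid))
  post[valid] <- exp(lp - .logSumExp(lp))
  dec <- which(valid)[which.max(lp)] - 1L
  list(posterior = post, decodedBin = dec)
}

#' Decode the running frames of the testing trials
#'
#' Per-frame naive-Bayes decoding; the error is the circular distance between
#' the true and decoded bin centres (0 to trackLength/2 cm).
#'
#' @param templates a [TemplateSet-class].
#' @param session a [CalciumSession-class].
#' @param activity cells x frames activity.
#' @param testTrials testing trial ids (defaults to the odd-numbered eligible
#'   trials).
#' @param runThresholdCmS running-speed threshold.
#' @param keepPosterior store the frames x bins posterior matrix.
#' @return a [DecodingResult-class].
#' @export
decodeSession <- function(templates, session, activity = NULL,
                          testTrials = NULL, runThresholdCmS = 5,
                          keepPosterior = FALSE) {
  stopifnot(is(templates, "TemplateSet"), is(session, "CalciumSession"))
  if (is.null(activity)) activity <- transientTraces(session)
  if (is.null(testTrials)) testTrials <- trainTestSplit(
    eligibleTrials(session))$test
  nBins <- ncol(templates@templates)
  bin <- .frameBins(session, testTrials, runThresholdCmS, nBins)
  frames <- which(!is.na(bin))
  if (!length(frames)) stop("no test frames")
  valid <- templates@validBins
  f <- templates@templates[, valid, drop = FALSE]
  lp <- crossprod(activity[, frames, drop = FALSE], log(f))
  lp <- sweep(lp, 2, templates@tau * colSums(f), "-")
  decIdx <- max.col(lp, ties.method = "first")
  decoded <- which(valid)[decIdx] - 1L
  trueBin <- bin[frames]
  tl <- trackLength(session)
  binSize <- tl / nBins
  err <- .circDistCm((decoded + 0.5) * binSize, (trueBin + 0.5) * binSize, tl)
  post <- matrix(numeric(0), 0, 0)
  if (keepPosterior) {
    post <- matrix(0, length(frames), nBins)
    post[, valid] <- exp(lp - apply(lp, 1, .logSumExp))
  }
  errorByBin <- vapply(0:(nBins - 1), function(b)
    if (any(trueBin == b)) mean(err[trueBin == b]) else NA_real_, numeric(1))
  new("DecodingResult", decodedBin = as.integer(decoded),
      trueBin = as.integer(trueBin), errorCm = err,
      frames = as.integer(frames), meanError = mean(err),
      errorByBin = errorByBin, posterior = post)
}

#' Train and test a decoder on one cell subset
#' @noRd
.decodeSubset <- function(session, activity, cells, split,
                          runThresholdCmS = 5, nBins = 40,
                          epsilonFrac = 0.01) {
  act <- activity[cells, , drop = FALSE]
  tmpl <- fitTemplates(session, act, split$train, runThresholdCmS, nBins,
                       epsilonFrac)
  decodeSession(tmpl, session, act, split$test, runThresholdCmS)
}

#' Compare decoding accuracy between cell groups
#'
#' Both groups are randomly subsampled to the same size — the smaller group's
#' size clamped to \[`minCells`, `maxCells`\] — and a decoder is trained
#' (even eligible trials) and tested (odd eligible trials) on each subsample;
#' the train/test frames are identical for every group. The subsampling is
#' repeated `nReps` times and errors averaged per group. Sessions whose
#' smaller group has fewer than `minCells` cells are excluded (error).
#'
#' @param session a [CalciumSession-class].
#' @param cellGroups named list of cell index vectors.
#' @param activity cells x frames activity.
#' @param nReps number of subsampling repetitions.
#' @param seed RNG seed.
#' @param minCells,maxCells decoding population size rule.
#' @inheritParams fitTemplates
#' @return named numeric vector of mean decoding errors (cm) per group.
#' @export
compareGroupsDecoding <- function(session, cellGroups, activity = NULL,
                                  nReps = 100, seed = 1, minCells = 10,
                                  maxCells = 100, runThresholdCmS = 5,
                                  nBins = 40, epsilonFrac = 0.01) {
  stopifnot(is(session, "CalciumSession"), is.list(cellGroups))
  if (is.null(activity)) activity <- transientTraces(session)
  sizes <- lengths(cellGroups)
  if (min(sizes) < minCells)
    stop("session excluded: smaller group has fewer than ", minCells,
         " cells")
  m <- min(max(min(sizes), minCells), maxCells)
  split <- trainTestSplit(eligibleTrials(session))
  set.seed(seed)
  errs <- matrix(NA_real_, nReps, length(cellGroups),
                 dimnames = list(NULL, names(cellGroups)))
  for (r in seq_len(nReps)) {
    for (g in seq_along(cellGroups)) {
      cells <- if (sizes[g] == m) cellGroups[[g]] else
        sample(cellGroups[[g]], m)
      errs[r, g] <- .decodeSubset(session, activity, cells, split,
                                  runThresholdCmS, nBins, epsilonFrac)@meanError
    }
  }
  colMeans(errs)
}

#' Per-decile decoding and the decile-group summary
#'
#' Trains and tests a decoder independently on each induction decile (all
#' cells of the decile). The low-induction summary is the mean error of
#' deciles 1-2 and the high-induction summary that of deciles 9-10.
#'
#' @param session a [CalciumSession-class].
#' @param decile per-cell decile assignment (1..10).
#' @param activity cells x frames activity.
#' @inheritParams fitTemplates
#' @return list(perDecile, low, high).
#' @export
decodeByDecile <- function(session, decile, activity = NULL,
                           runThresholdCmS = 5, nBins = 40,
                           epsilonFrac = 0.01) {
  stopifnot(is(session, "CalciumSession"))
  if (is.null(activity)) activity <- transientTraces(session)
  split <- trainTestSplit(eligibleTrials(session))
  perDecile <- vapply(1:10, function(d) {
    cells <- which(decile == d)
    if (length(cells) < 2) return(NA_real_)
    .decodeSubset(session, activity, cells, split, runThresholdCmS, nBins,
                  epsilonFrac)@meanError
  }, numeric(1))
  list(perDecile = perDecile,
       low = mean(perDecile[1:2], na.rm = TRUE),
       high = mean(perDecile[9:10], na.rm = TRUE))
}

#' Activity-match two cell groups on integrated dF/F
#'
#' Bin edges are ten equal-width bins of log10(alpha) over the whole
#' population. Within each bin, one cell per group is drawn per iteration:
#' whichever group's running matched-set mean alpha is higher draws from the
#' least active half of its remaining bin members while the other draws from
#' its most active half (the first draw in a bin is unconstrained). Drawing
#' stops in a bin when either group's members there are exhausted, so the
#' matched sets are equal-sized within every bin and their mean activities
#' are balanced. Cells with alpha = 0 are excluded.
#'
#' @param alpha per-cell integrated dF/F for the whole population.
#' @param groupHigh,groupLow cell indices of the two groups.
#' @param nBinsLog number of log10(alpha) bins.
#' @param seed RNG seed.
#' @return list(high, low) of matched cell indices (equal length).
#' @export
activityMatch <- function(alpha, groupHigh, groupLow, nBinsLog = 10,
                          seed = 1) {
  pop <- which(alpha > 0)
  groupHigh <- intersect(groupHigh, pop)
  groupLow <- intersect(groupLow, pop)
  la <- log10(alpha[pop])
  edges <- seq(min(la), max(la), length.out = nBinsLog + 1)
  binOf <- function(idx) {
    b <- findInterval(log10(alpha[idx]), edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    b
  }
  set.seed(seed)
  selH <- selL <- integer(0)
  drawHalf <- function(cand, lower) {
    ## candidates sorted by alpha; draw from the lower- or upper-alpha half
    o <- cand[order(alpha[cand])]
    k <- length(o)
    half <- if (lower) o[seq_len(ceiling(k / 2))] else
      o[(k - ceiling(k / 2) + 1):k]
    if (length(half) == 1) half else sample(half, 1)
  }
  for (b in seq_len(nBinsLog)) {
    remH <- groupHigh[binOf(groupHigh) == b]
    remL <- groupLow[binOf(groupLow) == b]
    while (length(remH) && length(remL)) {
      if (!length(selH) || !length(selL) ||
          mean(alpha[selH]) == mean(alpha[selL])) {
        dH <- if (length(remH) == 1) remH else sample(remH, 1)
        dL <- if (length(remL) == 1) remL else sample(remL, 1)
      } else if (mean(alpha[selH]) > mean(alpha[selL])) {
        dH <- drawHalf(remH, lower = TRUE)
        dL <- drawHalf(remL, lower = FALSE)
      } else {
        dH <- drawHalf(remH, lower = FALSE)
        dL <- drawHalf(remL, lower = TRUE)
      }
      selH <- c(selH, dH); remH <- setdiff(remH, dH)
      selL <- c(selL, dL); remL <- setdiff(remL, dL)
    }
  }
  list(high = selH, low = selL)
}
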