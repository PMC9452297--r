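## Behaviour: trial segmentation, lick classification, eligibility filtering,
## licking selectivity and a generic two-sided permutation test.

#' Segment a session into trials and classify licks
#'
#' Trials are cut at circular position wraps. Licks inside the reward zone
#' that occur after that trial's reward delivery are classified as
#' "consumption" licks; all others are "test" licks. Each trial record carries
#' its duration, test-lick count, manual-reward flag, the cumulative reward
#' volume delivered before the trial started, and the eligibility flag used
#' by all place-field analyses: at least 3 test licks, duration between
#' `minDurationS` and `maxDurationS`, no manual reward, and a cumulative
#' reward before the trial below `maxCumRewardMl`.
#'
#' @param x a [CalciumSession-class] with raw licks and rewards in metadata.
#' @param trialTypes optional character vector of per-trial types
#'   ("standard"/"crutch"/"probe"); defaults to types already present in
#'   `trials(x)` or "standard".
#' @param minLicks,minDurationS,maxDurationS,maxCumRewardMl eligibility rule.
#' @return the session with recomputed `trialId`, classified licks and a
#'   full `trials` table.
#' @export
annotateTrials <- function(x, trialTypes = NULL, minLicks = 3,
                           minDurationS = 4, maxDurationS = 60,
                           maxCumRewardMl = 1.2) {
  stopifnot(is(x, "CalciumSession"))
  pos <- position(x)
  tl <- trackLength(x)
  fr <- frameRate(x)
  ## new trial whenever position wraps (large negative jump)
  wrap <- c(FALSE, diff(pos) < -tl / 2)
  tid <- cumsum(wrap) + 1L
  nTrials <- max(tid)

  lk <- licks(x)
  rw <- rewards(x)
  if (nrow(lk)) {
    if (is.null(lk$position)) lk$position <- pos[lk$frame]
    miss <- is.na(lk$position)
    lk$position[miss] <- pos[lk$frame[miss]]
  }
  lk$trial <- tid[lk$frame]
  if (nrow(rw)) rw$trial <- tid[rw$frame]

  rz <- rewardZone(x)
  inZone <- function(p) p >= rz[1] & p < rz[2]
  if (nrow(lk)) lk$kind <- "test"
  if (nrow(lk) && nrow(rw)) {
    rewFrame <- rep(NA_integer_, nTrials)
    rewFrame[rw$trial] <- rw$frame
    after <- !is.na(rewFrame[lk$trial]) & lk$frame > rewFrame[lk$trial]
    lk$kind[inZone(lk$position) & after] <- "consumption"
  }

  if (is.null(trialTypes)) {
    tt <- trials(x)
    trialTypes <- if (!is.null(tt) && "type" %in% names(tt) &&
                      nrow(tt) == nTrials) tt$type else
                    rep("standard", nTrials)
  }
  stopifnot(length(trialTypes) == nTrials)

  duration <- as.vector(table(factor(tid, levels = seq_len(nTrials)))) / fr
  if (any(duration <= 0)) stop("trial with nonpositive duration")
  nTestLicks <- vapply(seq_len(nTrials), function(t)
    sum(lk$trial == t & lk$kind == "test"), integer(1))
  manual <- vapply(seq_len(nTrials), function(t)
    any(rw$trial == t & rw$manual), logical(1))
  rewardVol <- vapply(seq_len(nTrials), function(t)
    sum(rw$volume[rw$trial == t]), numeric(1))
  cumBefore <- cumsum(c(0, rewardVol))[seq_len(nTrials)]
  eligible <- nTestLicks >= minLicks & duration >= minDurationS &
    duration <= maxDurationS & !manual & cumBefore < maxCumRewardMl

  trialTab <- data.frame(
    trial = seq_len(nTrials), type = trialTypes, duration_s = duration,
    n_test_licks = nTestLicks, manual_reward = manual,
    reward_volume_ml = rewardVol, cum_reward_before_ml = cumBefore,
    eligible = eligible)

  SummarizedExperiment::colData(x)$trialId <- tid
  S4Vectors::metadata(x)$licks <- lk
  S4Vectors::metadata(x)$rewards <- rw
  S4Vectors::metadata(x)$trials <- trialTab
  validObject(x)
  x
}

#' Trial ids passing the eligibility rule
#' @param x a [CalciumSession-class] with an annotated trials table.
#' @return integer vector of eligible trial ids.
#' @export
eligibleTrials <- function(x) {
  tt <- trials(x)
  if (is.null(tt)) stop("run annotateTrials() first")
  tt$trial[tt$eligible]
}

#' Licking selectivity of a session
#'
#' Compares the number of test licks in the 10 cm immediately before the
#' reward-zone start (anticipatory licking) with the number in an equally
#' sized zone on the diametrically opposite side of the circular track:
#' (pre - opposite) / (pre + opposite). Consumption licks are excluded.
#' Returns `NA` when both counts are zero.
#'
#' @param x a [CalciumSession-class] (licks classified).
#' @param zoneWidthCm width of the two comparison zones.
#' @return selectivity in \[-1, 1\], or `NA`.
#' @export
lickingSelectivity <- function(x, zoneWidthCm = 10) {
  stopifnot(is(x, "CalciumSession"))
  tl <- trackLength(x)
  rz <- rewardZone(x)
  preFrom <- (rz[1] - zoneWidthCm) %% tl
  oppFrom <- (preFrom + tl / 2) %% tl
  if (zoneWidthCm > tl / 2) stop("comparison zones overlap")
  lk <- licks(x)
  lk <- lk[lk$kind == "test", , drop = FALSE]
  p <- lk$position
  inArc <- function(from) {
    to <- (from + zoneWidthCm) %% tl
    if (from < to) p >= from & p < to else p >= from | p < to
  }
  pre <- sum(inArc(preFrom))
  opp <- sum(inArc(oppFrom))
  if (pre + opp == 0) return(NA_real_)
  (pre - opp) / (pre + opp)
}

#' Two-sided permutation test on a difference of means
#'
#' The observed statistic is mean(a) - mean(b). The null is built by pooling
#' both groups and relabelling `nShuffles` times; the p-value is the fraction
#' of shuffles with |null| >= |observed|, with add-one smoothing so that
#' p >= 1/(nShuffles + 1).
#'
#' @param a,b numeric vectors (both nonempty).
#' @param nShuffles number of relabellings.
#' @param seed RNG seed.
#' @return p-value.
#' @export
permutationTestTwoSided <- function(a, b, nShuffles = 1000, seed = 1) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  if (nShuffles < 1) stop("nShuffles must be >= 1")
  obs <- mean(a) - mean(b)
  pooled <- c(a, b)
  nA <- length(a)
  set.seed(seed)
  null <- vapply(seq_len(nShuffles), function(i) {
    idx <- sample.int(length(pooled), nA)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1))
  (1 + sum(abs(null) >= abs(obs))) / (nShuffles + 1)
}

#' Stable-performance session filter
#'
#' Marks the first session in which licking selectivity reached `threshold`
#' and every session thereafter.
#'
#' @param selectivity per-session selectivity values, in time order.
#' @param threshold selectivity criterion.
#' @return logical inclusion mask (all-FALSE if no session qualifies).
#' @export
stableSessionFilter <- function(selectivity, threshold = 0.6) {
  ok <- !is.na(selectivity) & selectivity >= threshold
  cumsum(ok) > 0
}
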