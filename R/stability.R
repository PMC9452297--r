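## Cross-day place-field stability: per-cell tuning correlations, activity-
## weighted stability maps, zone summaries, sign-flip permutation tests on
## group differences, and the remapping contingency analysis.

#' Per-cell tuning correlation between two sessions
#'
#' Pearson correlation of each cell's spatially binned activity vector on the
#' reference and target sessions. Cells with zero variance on either session
#' are skipped (NA).
#'
#' @param refTuning,targetTuning cells x bins matrices over the same cells
#'   (rows aligned).
#' @return per-cell correlation vector x.
#' @export
placefieldCorrelation <- function(refTuning, targetTuning) {
  stopifnot(all(dim(refTuning) == dim(targetTuning)))
  vapply(seq_len(nrow(refTuning)), function(i) {
    a <- refTuning[i, ]; b <- targetTuning[i, ]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }, numeric(1))
}

#' Activity-weighted stability map for one cell group
#'
#' Each cell's reference tuning is normalized to sum to one over bins, so
#' every place field contributes equally regardless of activity level; the
#' stability at bin i is the weighted mean of the per-cell correlations x
#' with those weights. Bins with zero total weight are NA. At least
#' `minCells` cells are required.
#'
#' @param x per-cell reference-to-target tuning correlations
#'   ([placefieldCorrelation()]); NA cells are dropped.
#' @param refTuning cells x bins reference binned activity (same rows as x);
#'   the smoothed mean tuning by convention.
#' @param group group label.
#' @param dSessions target minus reference session index.
#' @param minCells minimum group size.
#' @return a [StabilityMap-class].
#' @export
stabilityMap <- function(x, refTuning, group = "all", dSessions = 1L,
                         minCells = 20) {
  stopifnot(nrow(refTuning) == length(x))
  keep <- which(!is.na(x) & rowSums(refTuning, na.rm = TRUE) > 0)
  if (length(keep) < minCells)
    stop("session pair excluded: fewer than ", minCells, " usable cells")
  x <- x[keep]
  w <- refTuning[keep, , drop = FALSE]
  w[is.na(w)] <- 0
  w <- w / rowSums(w)
  num <- colSums(w * x)
  den <- colSums(w)
  stab <- ifelse(den > 0, num / den, NA_real_)
  new("StabilityMap", stability = stab, x = x, weights = w,
      cellIds = as.integer(keep), group = group,
      dSessions = as.integer(dSessions), nCells = length(keep))
}

#' Zone summary of a stability map
#'
#' Unweighted mean of the non-missing per-bin stability within each zone.
#' Default zones: peri-reward = reward zone extended by `periMarginCm` on
#' each side; no-reward = all remaining bins.
#'
#' @param map a [StabilityMap-class] (or a plain per-bin numeric vector).
#' @param rewardZone numeric(2) reward zone in cm.
#' @param trackLength track length in cm.
#' @param periMarginCm extension of the reward zone on each side.
#' @param zones optional named list of 0-based bin vectors overriding the
#'   default geometry.
#' @return named numeric vector of per-zone means.
#' @export
zoneSummary <- function(map, rewardZone, trackLength = 200,
                        periMarginCm = 20, zones = NULL) {
  stab <- if (is(map, "StabilityMap")) map@stability else map
  nBins <- length(stab)
  if (is.null(zones)) {
    peri <- .binsInZone(rewardZone[1] - periMarginCm,
                        rewardZone[2] + periMarginCm, trackLength, nBins)
    zones <- list(peri_reward = peri,
                  no_reward = setdiff(0:(nBins - 1), peri))
  }
  if (any(lengths(zones) == 0)) stop("empty zone")
  vapply(zones, function(b) mean(stab[b + 1], na.rm = TRUE), numeric(1))
}

#' Sign-flip permutation test on paired stability-map differences
#'
#' For paired per-bin maps from two groups over several session-to-session
#' comparisons, the statistic is the mean over comparisons of (A - B) per
#' bin. The null randomly flips the group assignment within each comparison
#' (sign-flip), two-sided, with add-one smoothing. The zone contrast is the
#' difference of the mean A - B between the peri-reward and no-reward zones
#' under the same null.
#'
#' @param mapsA,mapsB comparisons x bins matrices of per-bin stability for
#'   the two groups (rows paired).
#' @param rewardZone,trackLength,periMarginCm,zones zone geometry as in
#'   [zoneSummary()].
#' @param nShuffles number of sign-flip shuffles.
#' @param seed RNG seed.
#' @return list(perBinDiff, perBinP, zoneContrast, zoneContrastP).
#' @export
stabilityDifferenceTest <- function(mapsA, mapsB, rewardZone,
                                    trackLength = 200, periMarginCm = 20,
                                    zones = NULL, nShuffles = 1000,
                                    seed = 1) {
  stopifnot(all(dim(mapsA) == dim(mapsB)))
  nComp <- nrow(mapsA)
  if (nComp < 2) stop("need at least 2 paired comparisons")
  nBins <- ncol(mapsA)
  D <- mapsA - mapsB
  obsBin <- colMeans(D, na.rm = TRUE)
  if (is.null(zones)) {
    peri <- .binsInZone(rewardZone[1] - periMarginCm,
                        rewardZone[2] + periMarginCm, trackLength, nBins)
    zones <- list(peri_reward = peri,
                  no_reward = setdiff(0:(nBins - 1), peri))
  }
  zoneStat <- function(binDiff)
    mean(binDiff[zones[[1]] + 1], na.rm = TRUE) -
      mean(binDiff[zones[[2]] + 1], na.rm = TRUE)
  obsZone <- zoneStat(obsBin)
  set.seed(seed)
  cntBin <- numeric(nBins)
  cntZone <- 0
  for (s in seq_len(nShuffles)) {
    flip <- sample(c(-1, 1), nComp, replace = TRUE)
    nullBin <- colMeans(D * flip, na.rm = TRUE)
    cntBin <- cntBin + (abs(nullBin) >= abs(obsBin))
    cntZone <- cntZone + (abs(zoneStat(nullBin)) >= abs(obsZone))
  }
  list(perBinDiff = obsBin,
       perBinP = (1 + cntBin) / (nShuffles + 1),
       zoneContrast = obsZone,
       zoneContrastP = (1 + cntZone) / (nShuffles + 1))
}

#' Field gain/loss versus induction contingency across environments
#'
#' Among cells without a field in the first environment, compares the
#' probability of high induction in the second environment between cells
#' that gained a field there and cells that did not; among cells with a
#' field in E1, between cells that lost it and cells that kept it.
#' Significance by permutation of the induction labels.
#'
#' @param fieldE1,fieldE2 per-cell logical place-field flags in the two
#'   environments (tracked cells, aligned).
#' @param highInductionE2 per-cell logical: high induction in E2.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @return data.frame with one row per transition (gained vs not, lost vs
#'   kept): proportions, ratio and permutation p.
#' @export
remapContingency <- function(fieldE1, fieldE2, highInductionE2,
                             nPerm = 1000, seed = 1) {
  stopifnot(length(fieldE1) == length(fieldE2),
            length(fieldE1) == length(highInductionE2))
  one <- function(subset, eventFlag, name) {
    a <- highInductionE2[subset & eventFlag]
    b <- highInductionE2[subset & !eventFlag]
    if (!length(a) || !length(b)) stop("empty contingency cell for ", name)
    pEvent <- mean(a)
    pNo <- mean(b)
    p <- permutationTestTwoSided(as.numeric(a), as.numeric(b),
                                 nShuffles = nPerm, seed = seed)
    data.frame(transition = name, p_high_given_event = pEvent,
               p_high_given_none = pNo,
               ratio = if (pNo > 0) pEvent / pNo else Inf, p_value = p)
  }
  rbind(
    one(!fieldE1, fieldE2, "gained"),
    one(fieldE1, !fieldE2, "lost")
  )
}
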