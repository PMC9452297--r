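## Position-independent trial-wise co-activation analysis: place-field
## activation matrix, within-group correlations, affinity-propagation
## clustering, chance-normalized co-membership, and cross-day correlations.

#' Trial-wise place-field activation matrix
#'
#' Entry (t, c) is the mean binned activity of place cell c within its own
#' field bins on eligible trial t — a position-independent readout of how
#' strongly each cell's field fired on each lap. Trials on which none of the
#' cell's field bins were visited give NA.
#'
#' @param tuning a [SpatialTuningSet-class].
#' @param cells cell indices to include; defaults to all place cells.
#' @return trials x cells matrix with the cell indices as column names.
#' @export
activationMatrix <- function(tuning, cells = which(isPlaceCell(tuning))) {
  stopifnot(is(tuning, "SpatialTuningSet"))
  if (length(cells) < 2) stop("need at least 2 place cells")
  if (!all(tuning@placeCell[cells]))
    stop("all requested cells must have a place field")
  nTrial <- dim(tuning@perTrial)[1]
  if (nTrial < 2) stop("need at least 2 eligible trials")
  nBins <- dim(tuning@perTrial)[2]
  out <- matrix(NA_real_, nTrial, length(cells),
                dimnames = list(NULL, as.character(cells)))
  for (j in seq_along(cells)) {
    c <- cells[j]
    flds <- tuning@fields[tuning@fields$cell == c, , drop = FALSE]
    bins <- unique(unlist(lapply(seq_len(nrow(flds)), function(k)
      (flds$start_bin[k] + 0:(flds$n_bins[k] - 1)) %% nBins))) + 1L
    sub <- tuning@perTrial[, bins, c, drop = FALSE]
    out[, j] <- rowMeans(matrix(sub, nTrial), na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Mean pairwise correlation of activation within groups
#'
#' For each group, the mean over distinct cell pairs of the Pearson
#' correlation of their trial-wise activation vectors, computed over the
#' trials where both are non-missing; pairs sharing fewer than `minShared`
#' trials are skipped.
#'
#' @param mat trials x cells activation matrix (columns named by cell).
#' @param groups named list of cell-index vectors (matched against column
#'   names).
#' @param minShared minimum shared trials per pair.
#' @return named numeric vector of per-group means (NA when no pair
#'   qualifies).
#' @export
withinGroupCorrelation <- function(mat, groups, minShared = 3) {
  vapply(groups, function(g) {
    cols <- which(colnames(mat) %in% as.character(g))
    if (length(cols) < 2) stop("each group needs at least 2 cells present")
    rs <- c()
    for (i in seq_along(cols)[-length(cols)])
      for (j in (i + 1):length(cols)) {
        a <- mat[, cols[i]]; b <- mat[, cols[j]]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < minShared) next
        if (sd(a[ok]) == 0 || sd(b[ok]) == 0) next
        rs <- c(rs, cor(a[ok], b[ok]))
      }
    if (length(rs)) mean(rs) else NA_real_
  }, numeric(1))
}

#' Affinity-propagation clustering of a similarity matrix
#'
#' Frey-Dueck message passing: responsibilities and availabilities are
#' iterated with damping until the exemplar set is stable for `convIter`
#' iterations or `maxIter` is reached. The diagonal of the similarity matrix
#' is replaced by the (common) preference; larger preferences yield more
#' clusters.
#'
#' @param S symmetric similarity matrix (missing entries must be imputed
#'   before calling; see [clusterCells()]).
#' @param preference common self-similarity.
#' @param damping damping factor in (0, 1).
#' @param maxIter iteration cap.
#' @param convIter iterations of stable exemplars declaring convergence.
#' @return list(labels = exemplar index per point, exemplars, converged,
#'   iterations).
#' @export
affinityPropagation <- function(S, preference = -1, damping = 0.9,
                                maxIter = 5000, convIter = 100) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (any(is.na(S))) stop("similarity matrix has missing entries")
  n <- nrow(S)
  if (n == 1) return(list(labels = 1L, exemplars = 1L, converged = TRUE,
                          iterations = 0L))
  diag(S) <- preference
  R <- A <- matrix(0, n, n)
  lastEx <- NULL
  stable <- 0L
  it <- 0L
  converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    ## responsibilities
    AS <- A + S
    i1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(seq_len(n), i1)]
    AS[cbind(seq_len(n), i1)] <- -Inf
    m2 <- AS[cbind(seq_len(n), max.col(AS, ties.method = "first"))]
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), i1)] <- S[cbind(seq_len(n), i1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    ## availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- cs - diag(Rp) # sum_{i' != k} max(0, R[i'k])
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, lastEx)) stable <- stable + 1L else stable <- 0L
    lastEx <- ex
    if (length(ex) && stable >= convIter) {
      converged <- TRUE
      break
    }
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (!length(ex)) ex <- which.max(diag(A) + diag(R))
  lab <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  lab[ex] <- ex
  list(labels = lab, exemplars = ex, converged = converged, iterations = it)
}

#' Cluster cells by trial-wise activation correlation
#'
#' Similarity is the cell x cell Pearson correlation of trial-wise
#' place-field activation (missing activation entries imputed as 0 for the
#' correlation, which requires a complete matrix); clustering is affinity
#' propagation with the given preference and iteration cap.
#'
#' @param mat trials x cells activation matrix.
#' @param preference affinity-propagation preference.
#' @param damping damping factor.
#' @param maxIter iteration cap.
#' @return list(labels, exemplars, converged, similarity).
#' @export
clusterCells <- function(mat, preference = -1, damping = 0.9,
                         maxIter = 5000) {
  m <- mat
  m[is.na(m)] <- 0
  S <- suppressWarnings(cor(m))
  S[is.na(S)] <- 0
  ap <- affinityPropagation(S, preference = preference, damping = damping,
                            maxIter = maxIter)
  c(ap[c("labels", "exemplars", "converged")], list(similarity = S))
}

#' Within-group same-cluster probability relative to chance
#'
#' The observed probability that two cells of the same group share a cluster,
#' divided by the mean of the same statistic when group labels are permuted
#' over the clustered cells (`nPerm` permutations, fixed clustering). A
#' single-cluster partition gives ratio 1 and is flagged.
#'
#' @param labels per-cell cluster labels.
#' @param groups named list of cell-index vectors (indices into `labels`).
#' @param nPerm number of label permutations.
#' @param seed RNG seed.
#' @return data.frame: group, observed, chance, ratio, degenerate.
#' @export
sameClusterVsChance <- function(labels, groups, nPerm = 1000, seed = 1) {
  n <- length(labels)
  sameProb <- function(idx) {
    if (length(idx) < 2) stop("each group needs at least 2 cells")
    pairs <- utils::combn(idx, 2)
    mean(labels[pairs[1, ]] == labels[pairs[2, ]])
  }
  degenerate <- length(unique(labels)) == 1
  set.seed(seed)
  res <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    obs <- sameProb(idx)
    ch <- mean(vapply(seq_len(nPerm), function(p)
      sameProb(sample.int(n, length(idx))), numeric(1)))
    data.frame(group = g, observed = obs, chance = ch,
               ratio = if (degenerate) 1 else obs / ch,
               degenerate = degenerate)
  })
  do.call(rbind, res)
}

#' Cross-day within-group activation correlation
#'
#' Group membership (e.g. Fos-high / Fos-low) is fixed by induction on the
#' reference session; the within-group correlation is then computed on the
#' target session's activation matrix over the cells present and fielded
#' there.
#'
#' @param targetMat trials x cells activation matrix of the target session,
#'   columns named by global cell id.
#' @param refGroups named list of global cell-id vectors defined on the
#'   reference session.
#' @param minShared minimum shared trials per pair.
#' @return named numeric vector of per-group correlations.
#' @export
crossdayWithinGroup <- function(targetMat, refGroups, minShared = 3) {
  present <- lapply(refGroups, function(g)
    g[as.character(g) %in% colnames(targetMat)])
  if (any(lengths(present) < 2))
    stop("fewer than 2 group members present on the target session")
  withinGroupCorrelation(targetMat, present, minShared)
}
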