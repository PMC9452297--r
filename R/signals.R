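## Trace preprocessing: dF/F baselining and significant-transient detection
## with an empirical per-duration false-positive-rate criterion.

#' Compute dF/F from a raw fluorescence trace
#'
#' The baseline at each frame is the 30th percentile of the raw trace in a
#' moving window (60 s by default), centred on the frame and truncated at the
#' edges of the recording. dF/F = (raw - baseline) / baseline.
#'
#' @param raw numeric raw fluorescence trace.
#' @param frameRate frames per second.
#' @param windowS window length in seconds.
#' @param prob baseline percentile (0.3 = 30th).
#' @param centered if `FALSE`, use a trailing window instead of a centred one.
#' @return numeric dF/F trace of the same length.
#' @export
computeDff <- function(raw, frameRate, windowS = 60, prob = 0.3,
                       centered = TRUE) {
  if (any(!is.finite(raw))) stop("raw trace contains non-finite values")
  n <- length(raw)
  w <- round(windowS * frameRate)
  if (n <= w) stop("trace shorter than the baseline window")
  half <- w %/% 2
  baseline <- vapply(seq_len(n), function(i) {
    if (centered) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
    } else {
      lo <- max(1L, i - w + 1L); hi <- i
    }
    quantile(raw[lo:hi], prob, names = FALSE)
  }, numeric(1))
  if (any(baseline <= 0))
    stop("baseline <= 0: corrupt input (raw fluorescence must stay positive)")
  (raw - baseline) / baseline
}

#' Detect significant calcium transients in a dF/F trace
#'
#' The trace is standardized by subtracting its median and dividing by its
#' standard deviation. For each threshold t in `thresholds` (in s.d. units),
#' maximal runs of frames strictly above +t are candidate transients. A
#' candidate of length n frames is significant at t if the empirical false
#' positive rate
#' \deqn{FPR(t, n) = \frac{\#\{\text{runs below } -t \text{ of length} \ge n\}}
#'                       {\#\{\text{runs above } +t \text{ of length} \ge n\}}}
#' is below `fprMax`. The final mask is the union of significant frames over
#' all thresholds; runs separated by fewer than 2 non-significant frames are
#' then merged (the gap frames recover their original dF/F), and runs shorter
#' than 2 frames are dropped. The returned trace carries the original dF/F on
#' significant frames and exact zeros elsewhere.
#'
#' @param dffTrace numeric dF/F trace (>= 10 frames).
#' @param frameRate frames per second (for the summary statistics).
#' @param thresholds threshold grid in s.d. units.
#' @param fprMax false-positive-rate bound.
#' @return a [TransientTrace-class].
#' @export
detectSignificantTransients <- function(dffTrace, frameRate = 30,
                                        thresholds = seq(1, 4, by = 0.2),
                                        fprMax = 0.001) {
  if (any(!is.finite(dffTrace))) stop("trace contains non-finite values")
  if (length(dffTrace) < 10) stop("trace must have at least 10 frames")
  s <- sd(dffTrace)
  if (s == 0) stop("zero-variance trace cannot be standardized")
  z <- (dffTrace - median(dffTrace)) / s

  mask <- logical(length(z))
  accept <- list() # per accepted run: threshold, length, fpr (for auditing)
  nGe <- function(lengths, n) {
    ## number of run lengths >= each n, via sorted counts
    if (!length(lengths)) return(rep(0L, length(n)))
    s <- sort(lengths)
    length(s) - findInterval(n - 1L, s)
  }
  for (t in thresholds) {
    pos <- .findRuns(z > t)
    if (!pos$n) next
    neg <- .findRuns(z < -t)
    nPos <- nGe(pos$length, pos$length) # includes the candidate itself, >= 1
    nNeg <- nGe(neg$length, pos$length)
    fpr <- nNeg / nPos
    for (k in which(fpr < fprMax)) {
      mask[pos$start[k]:pos$end[k]] <- TRUE
      accept[[length(accept) + 1L]] <-
        c(start = pos$start[k], end = pos$end[k], t = t, n = pos$length[k],
          fpr = fpr[k])
    }
  }

  ## merge runs separated by < 2 frames (gap of 0 or 1 non-significant frames)
  runs <- .findRuns(mask)
  if (runs$n > 1) {
    for (k in seq_len(runs$n - 1L)) {
      gap <- runs$start[k + 1L] - runs$end[k] - 1L
      if (gap < 2L) mask[runs$end[k]:runs$start[k + 1L]] <- TRUE
    }
  }
  ## drop runs shorter than 2 frames
  runs <- .findRuns(mask)
  for (k in which(runs$length < 2L))
    mask[runs$start[k]:runs$end[k]] <- FALSE

  out <- dffTrace
  out[!mask] <- 0

  runs <- .findRuns(mask)
  acceptTab <- if (length(accept)) as.data.frame(do.call(rbind, accept)) else
    data.frame(start = numeric(0), end = numeric(0), t = numeric(0),
               n = numeric(0), fpr = numeric(0))
  events <- .transientEvents(out, runs, acceptTab, frameRate)
  stats <- .transientSummary(events, out, length(out), frameRate)
  new("TransientTrace", dff = out, mask = mask, events = events,
      stats = stats, frameRate = frameRate)
}

#' @noRd
.transientEvents <- function(maskedDff, runs, acceptTab, frameRate) {
  if (!runs$n) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_frames = integer(0), peak = numeric(0),
                      integral = numeric(0), accept_t = numeric(0),
                      accept_n = numeric(0)))
  }
  peak <- integral <- numeric(runs$n)
  at <- an <- rep(NA_real_, runs$n)
  for (k in seq_len(runs$n)) {
    seg <- maskedDff[runs$start[k]:runs$end[k]]
    peak[k] <- max(seg)
    integral[k] <- sum(seg) / frameRate
    if (nrow(acceptTab)) {
      hit <- acceptTab$start >= runs$start[k] & acceptTab$end <= runs$end[k]
      if (any(hit)) {
        ## record the most lenient accepting (threshold, length) pair
        i <- which(hit)[which.min(acceptTab$t[hit])]
        at[k] <- acceptTab$t[i]; an[k] <- acceptTab$n[i]
      }
    }
  }
  data.frame(start_frame = runs$start, end_frame = runs$end,
             duration_frames = runs$length, peak = peak, integral = integral,
             accept_t = at, accept_n = an)
}

#' @noRd
.transientSummary <- function(events, maskedDff, nFrames, frameRate) {
  empty <- nrow(events) == 0
  list(
    transients_per_second = nrow(events) / (nFrames / frameRate),
    mean_duration_s = if (empty) 0 else mean(events$duration_frames) / frameRate,
    mean_peak = if (empty) 0 else mean(events$peak),
    mean_integral = if (empty) 0 else mean(events$integral),
    alpha = sum(maskedDff) / frameRate,
    empty = empty
  )
}

#' Summary statistics of a TransientTrace
#'
#' Rate, mean duration, mean peak, mean per-transient integral and integrated
#' dF/F (alpha). With no transients the means are defined as 0 and the
#' `empty` flag is set.
#'
#' @param tr a [TransientTrace-class].
#' @return named list of statistics.
#' @export
summarizeTransients <- function(tr) {
  stopifnot(is(tr, "TransientTrace"))
  tr@stats
}

#' Detect significant transients for every cell of a session
#'
#' Applies [detectSignificantTransients()] row-wise to the `"dff"` assay and
#' stores the masked traces as a `"transients"` assay, per-cell statistics in
#' `metadata(x)$transientStats` and per-transient records in
#' `metadata(x)$transientEvents`.
#'
#' @param x a [CalciumSession-class] with a `"dff"` assay.
#' @inheritParams detectSignificantTransients
#' @return the session with the added assay and metadata.
#' @export
detectTransients <- function(x, thresholds = seq(1, 4, by = 0.2),
                             fprMax = 0.001) {
  stopifnot(is(x, "CalciumSession"))
  mat <- dff(x)
  if (!nrow(mat)) stop("session has no traces")
  fr <- frameRate(x)
  out <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  statRows <- vector("list", nrow(mat))
  evRows <- vector("list", nrow(mat))
  for (i in seq_len(nrow(mat))) {
    tr <- detectSignificantTransients(mat[i, ], frameRate = fr,
                                      thresholds = thresholds, fprMax = fprMax)
    out[i, ] <- tr@dff
    s <- tr@stats
    statRows[[i]] <- data.frame(cell = i,
                                transients_per_second = s$transients_per_second,
                                mean_duration_s = s$mean_duration_s,
                                mean_peak = s$mean_peak,
                                mean_integral = s$mean_integral,
                                alpha = s$alpha, empty = s$empty)
    if (nrow(tr@events)) evRows[[i]] <- cbind(cell = i, tr@events)
  }
  SummarizedExperiment::assay(x, "transients") <- out
  S4Vectors::metadata(x)$transientStats <- do.call(rbind, statRows)
  S4Vectors::metadata(x)$transientEvents <-
    if (length(ev <- Filter(Negate(is.null), evRows))) do.call(rbind, ev) else
      cbind(cell = integer(0), .transientEvents(numeric(0),
            list(start = integer(0), end = integer(0), length = integer(0),
                 n = 0L), data.frame(), fr))
  x
}
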