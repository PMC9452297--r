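## Internal helpers shared across modules: run finding on logical vectors,
## circular geometry on the track, and numerically stable normalization.

#' Find maximal runs of TRUE in a logical vector
#'
#' @param x logical vector (NA treated as FALSE).
#' @return list with fields `start`, `end` (1-based, inclusive), `length` and
#'   `n` (number of runs).
#' @noRd
.findRuns <- function(x) {
  x <- !is.na(x) & x
  if (!any(x)) {
    return(list(start = integer(0), end = integer(0), length = integer(0),
                n = 0L))
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(start = starts[keep], end = ends[keep], length = r$lengths[keep],
       n = sum(keep))
}

#' Maximal circular runs of TRUE over bins 0..n-1
#'
#' Bin n-1 is adjacent to bin 0. A run covering every bin is returned as a
#' single run of length n starting at bin 0.
#'
#' @param x logical vector over bins.
#' @return data.frame with `start` (0-based bin), `length`; bins of the run are
#'   `(start + 0:(length-1)) %% n`.
#' @noRd
.circularRuns <- function(x) {
  n <- length(x)
  x <- !is.na(x) & x
  if (all(x)) {
    return(data.frame(start = 0L, length = n))
  }
  if (!any(x)) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  ## rotate so that the vector starts on a FALSE bin, find linear runs, rotate back
  first_false <- which(!x)[1L]
  rot <- c(x[first_false:n], x[seq_len(first_false - 1L)])
  runs <- .findRuns(rot)
  data.frame(start = (runs$start - 1L + first_false - 1L) %% n,
             length = runs$length)
}

#' Circular distance between positions on the track
#' @noRd
.circDistCm <- function(a, b, trackLength) {
  d <- abs(a - b) %% trackLength
  pmin(d, trackLength - d)
}

#' Unit-sum Gaussian kernel on the circle of n bins
#' @noRd
.circGaussKernel <- function(n, sigma) {
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-d^2 / (2 * sigma^2))
  k / sum(k)
}

#' log-sum-exp
#' @noRd
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Which bins (0-based) fall inside a cm interval on the circular track
#'
#' The interval is half-open [from, to) in cm and may wrap past trackLength.
#' A bin belongs to the interval if its centre does.
#' @noRd
.binsInZone <- function(from, to, trackLength, nBins) {
  binSize <- trackLength / nBins
  centres <- (0:(nBins - 1) + 0.5) * binSize
  from <- from %% trackLength
  to <- to %% trackLength
  if (from <= to && !isTRUE(all.equal(from, to))) {
    inzone <- centres >= from & centres < to
  } else {
    inzone <- centres >= from | centres < to
  }
  which(inzone) - 1L
}

#' Deterministic seed for a named substream of a master seed
#'
#' Keeps derived seeds in the 32-bit integer range.
#' @noRd
.substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
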