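## Fos fold-induction quantification from pre/post GFP images: background
## normalization, per-cell circular ROI values, decile grouping, and the
## time-course standardization.

#' 2-D median filter with reflective padding
#'
#' @param img numeric matrix.
#' @param sizePx odd window edge length in pixels.
#' @return filtered matrix of the same shape.
#' @export
medianFilter2d <- function(img, sizePx) {
  if (sizePx < 1 || sizePx %% 2 != 1) stop("window size must be odd")
  if (sizePx == 1) return(img)
  r <- (sizePx - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  if (r >= n || r >= m) stop("window larger than image")
  ri <- c(r:1, 1:n, n:(n - r + 1))
  ci <- c(r:1, 1:m, m:(m - r + 1))
  pad <- img[ri, ci]
  ## EBImage's constant-time median filter works on [0, 1]; rescale around it
  lo <- min(pad); hi <- max(pad)
  if (hi == lo) return(matrix(lo, n, m))
  f <- EBImage::medianFilter((pad - lo) / (hi - lo), r)
  out <- as.matrix(f)[r + seq_len(n), r + seq_len(m)] * (hi - lo) + lo
  out
}

#' Background-normalized fold-induction map
#'
#' The registered post-behaviour image is divided by the pre-behaviour image;
#' the ratio is then divided by a background image obtained by 2-D median
#' filtering the ratio with a square window of edge ~50 um (rounded to the
#' nearest odd pixel count, reflective padding). This removes smooth
#' brightness changes across the field of view while leaving sparse nuclear
#' GFP signal, which is much smaller than the window, intact. Excluded or
#' nonpositive-pre pixels propagate NA.
#'
#' @param preImg,postImg registered 2-D images (matrices, same shape).
#' @param umPerPx microns per pixel.
#' @param exclusionMask optional logical matrix of artefact pixels to drop.
#' @param windowUm median-filter window edge in microns.
#' @return list(fold = normalized fold map (NA at excluded pixels),
#'   background, ratio, windowPx).
#' @export
foldInductionMap <- function(preImg, postImg, umPerPx,
                             exclusionMask = NULL, windowUm = 50) {
  stopifnot(all(dim(preImg) == dim(postImg)))
  if (is.null(exclusionMask))
    exclusionMask <- matrix(FALSE, nrow(preImg), ncol(preImg))
  stopifnot(all(dim(exclusionMask) == dim(preImg)))
  if (any(preImg[!exclusionMask] <= 0))
    stop("nonpositive pre-image pixels outside the exclusion mask")
  ratio <- postImg / preImg
  ratio[exclusionMask] <- NA_real_
  wPx <- round(windowUm / umPerPx)
  if (wPx %% 2 == 0) wPx <- wPx + 1L
  wPx <- max(wPx, 1L)
  filled <- ratio
  if (any(exclusionMask))
    filled[exclusionMask] <- median(ratio, na.rm = TRUE)
  bg <- medianFilter2d(filled, wPx)
  fold <- ratio / bg
  fold[exclusionMask] <- NA_real_
  list(fold = fold, background = bg, ratio = ratio, windowPx = wPx)
}

#' Per-cell fold-induction values from circular ROIs
#'
#' Averages the non-excluded fold-map pixels within a disc of diameter
#' `roiDiameterUm` centred on each cell body; discs are clipped at the image
#' border. Cells with more than half their ROI pixels excluded are flagged.
#'
#' @param foldMap fold-induction map (NA = excluded), as from
#'   [foldInductionMap()].
#' @param centroids data.frame or matrix with columns x, y in pixels (1-based).
#' @param umPerPx microns per pixel.
#' @param roiDiameterUm ROI diameter in microns.
#' @return data.frame: cell_id, fold_induction, n_px, excluded.
#' @export
cellFoldInduction <- function(foldMap, centroids, umPerPx,
                              roiDiameterUm = 10) {
  centroids <- as.data.frame(centroids)
  stopifnot(all(c("x", "y") %in% names(centroids)))
  rPx <- max((roiDiameterUm / 2) / umPerPx, 1)
  n <- nrow(foldMap); m <- ncol(foldMap)
  res <- lapply(seq_len(nrow(centroids)), function(i) {
    cx <- centroids$x[i]; cy <- centroids$y[i]
    if (cx < 1 || cx > m || cy < 1 || cy > n)
      stop("centroid ", i, " outside the image")
    xs <- max(1, floor(cx - rPx)):min(m, ceiling(cx + rPx))
    ys <- max(1, floor(cy - rPx)):min(n, ceiling(cy + rPx))
    grid <- expand.grid(y = ys, x = xs)
    d2 <- (grid$x - cx)^2 + (grid$y - cy)^2
    inDisc <- d2 <= rPx^2
    px <- foldMap[cbind(grid$y[inDisc], grid$x[inDisc])]
    nTot <- sum(inDisc)
    nOk <- sum(!is.na(px))
    if (nOk == 0) stop("ROI of cell ", i, " fully excluded")
    data.frame(cell_id = i, fold_induction = mean(px, na.rm = TRUE),
               n_px = nOk, excluded = nOk < nTot / 2)
  })
  do.call(rbind, res)
}

#' Assign induction deciles and high/low groups
#'
#' Cells are ranked by fold induction with ties broken deterministically by
#' cell id; decile d contains the cells with ranks in ((d-1)n/10, dn/10\].
#' The high group is the top 20% (deciles 9-10) and the low group the bottom
#' 20% (deciles 1-2); everything else is "mid". Excluded cells get no decile.
#'
#' @param values per-cell fold-induction values.
#' @param cellIds cell identifiers (default seq_along).
#' @param excluded logical exclusion flags.
#' @return data.frame: cell_id, fold_induction, decile, group, excluded,
#'   with a `degenerate` attribute set when all values are identical.
#' @export
assignInductionGroups <- function(values, cellIds = seq_along(values),
                                  excluded = rep(FALSE, length(values))) {
  ok <- which(!excluded & !is.na(values))
  if (length(ok) < 10) stop("need at least 10 non-excluded cells")
  o <- ok[order(values[ok], cellIds[ok])]
  n <- length(o)
  decile <- rep(NA_integer_, length(values))
  decile[o] <- as.integer(ceiling(seq_len(n) * 10 / n))
  group <- rep(NA_character_, length(values))
  group[!excluded & !is.na(values)] <- "mid"
  group[decile %in% c(1, 2)] <- "low"
  group[decile %in% c(9, 10)] <- "high"
  out <- data.frame(cell_id = cellIds, fold_induction = values,
                    decile = decile, group = group, excluded = excluded)
  attr(out, "degenerate") <- length(unique(values[ok])) == 1
  out
}

#' Standardize a GFP image time course and compute fold values per hour
#'
#' Each image is standardized by its own median and median absolute
#' deviation, then rescaled by a shared multiplicative factor A (the MAD of
#' pixel values across all images in the series) and additive offset B (the
#' median pixel value of all images). Fold maps are then computed against the
#' first (baseline) image as in [foldInductionMap()], and per-cell values are
#' averaged within 1-h bins from the series start.
#'
#' @param images list of matrices (same shape), in time order.
#' @param timesH acquisition times in hours from session start.
#' @param centroids cell centroids (see [cellFoldInduction()]).
#' @param umPerPx microns per pixel.
#' @param windowUm background window edge in microns.
#' @param roiDiameterUm ROI diameter in microns.
#' @return list(standardized, A, B, perCell (cells x images fold values),
#'   binned (data.frame hour_bin, cell_id, fold)).
#' @export
standardizeTimecourse <- function(images, timesH, centroids, umPerPx,
                                  windowUm = 50, roiDiameterUm = 10) {
  stopifnot(length(images) >= 2, length(timesH) == length(images))
  allPx <- unlist(lapply(images, as.numeric))
  A <- mad(allPx)
  B <- median(allPx)
  if (A <= 0) stop("series MAD must be positive")
  std <- lapply(images, function(im) {
    m <- median(im); s <- mad(as.numeric(im))
    if (s == 0) stop("MAD = 0 for an image in the series")
    (im - m) / s * A + B
  })
  base <- std[[1]]
  perCell <- sapply(seq_along(std)[-1], function(k) {
    fm <- foldInductionMap(base, std[[k]], umPerPx, windowUm = windowUm)
    cellFoldInduction(fm$fold, centroids, umPerPx, roiDiameterUm)$fold_induction
  })
  perCell <- cbind(1, perCell) # baseline against itself
  hourBin <- floor(timesH)
  rows <- list()
  for (hb in sort(unique(hourBin[-1]))) {
    cols <- which(hourBin == hb)
    cols <- cols[cols > 1]
    if (!length(cols)) next
    vals <- rowMeans(perCell[, cols, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      hour_bin = hb, cell_id = seq_along(vals), fold = vals)
  }
  list(standardized = std, A = A, B = B, perCell = perCell,
       binned = do.call(rbind, rows))
}

#' Read / write single-plane 16-bit TIFF images as plain matrices
#'
#' Thin wrappers for the registered 2-D mean images the fold-induction
#' functions consume, using the conventional 16-bit microscopy container:
#' values are integer counts in 0..65535 and are read back as stored.
#'
#' @param path file path.
#' @return `readImageTiff` returns a numeric matrix of raw counts.
#' @export
readImageTiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' @rdname readImageTiff
#' @param img numeric matrix of counts in 0..65535 (rounded on write).
#' @export
writeImageTiff <- function(img, path) {
  if (min(img) < 0 || max(img) > 65535)
    stop("image counts must lie in 0..65535")
  tiff::writeTIFF(round(img) / 65535, path, bits.per.sample = 16)
  invisible(path)
}
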