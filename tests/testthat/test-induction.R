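## Small synthetic image helpers: flat background with bright circular nuclei.
nucleiImage <- function(n = 96, centres, radiusPx = 3, level = 1,
                        nucleusLevel = 2) {
  img <- matrix(level, n, n)
  for (k in seq_len(nrow(centres))) {
    for (dy in -radiusPx:radiusPx) for (dx in -radiusPx:radiusPx) {
      if (dx^2 + dy^2 <= radiusPx^2) {
        y <- centres$y[k] + dy
        x <- centres$x[k] + dx
        if (y >= 1 && y <= n && x >= 1 && x <= n)
          img[y, x] <- nucleusLevel
      }
    }
  }
  img
}

bruteMedianFilter <- function(img, sizePx) {
  r <- (sizePx - 1) %/% 2
  n <- nrow(img); m <- ncol(img)
  ri <- c(r:1, 1:n, n:(n - r + 1))
  ci <- c(r:1, 1:m, m:(m - r + 1))
  pad <- img[ri, ci]
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m)
    out[i, j] <- median(pad[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

test_that("the reflect-padded median filter matches a brute-force oracle", {
  set.seed(8)
  img <- matrix(runif(48 * 48, 0.5, 2), 48)
  for (w in c(3, 7)) {
    got <- medianFilter2d(img, w)
    want <- bruteMedianFilter(img, w)
    expect_equal(got, want, tolerance = 1e-4) # filter backend quantization
  }
  expect_error(medianFilter2d(img, 4), "odd")
})

test_that("fold-induction maps cancel uniform changes and keep sparse nuclei", {
  umPerPx <- 1
  centres <- data.frame(x = c(20, 60, 80), y = c(30, 50, 20))
  pre <- nucleiImage(96, centres)

  ## post = 2 x pre: the background absorbs the global factor
  fm <- foldInductionMap(pre, 2 * pre, umPerPx)
  expect_true(all(abs(fm$fold - 1) < 1e-6))
  expect_equal(fm$windowPx, 51)

  ## post = pre: map of ones
  fm0 <- foldInductionMap(pre, pre, umPerPx)
  expect_true(all(abs(fm0$fold - 1) < 1e-6))

  ## doubling only the nuclei: nuclei pixels near 2, background near 1
  post <- nucleiImage(96, centres, nucleusLevel = 4)
  fm2 <- foldInductionMap(pre, post, umPerPx)
  nucleus <- fm2$fold[30, 20]
  bg <- fm2$fold[5, 5]
  expect_equal(nucleus, 2, tolerance = 0.05)
  expect_equal(bg, 1, tolerance = 0.05)

  ## invariance to global rescaling of either input image
  fmA <- foldInductionMap(3 * pre, post, umPerPx)
  expect_equal(fmA$fold, fm2$fold, tolerance = 1e-6)
  fmB <- foldInductionMap(pre, 5 * post, umPerPx)
  expect_equal(fmB$fold, fm2$fold, tolerance = 1e-6)

  ## exclusion mask propagates missing values
  excl <- matrix(FALSE, 96, 96)
  excl[1:10, 1:10] <- TRUE
  fmE <- foldInductionMap(pre, post, umPerPx, exclusionMask = excl)
  expect_true(all(is.na(fmE$fold[1:10, 1:10])))

  expect_error(foldInductionMap(pre - 1, post, umPerPx), "nonpositive")
})

test_that("circular ROIs average the fold map around each centroid", {
  umPerPx <- 1
  fold <- matrix(1.5, 64, 64)
  cells <- data.frame(x = c(10, 32, 64), y = c(10, 32, 2))
  v <- cellFoldInduction(fold, cells, umPerPx)
  expect_equal(v$fold_induction, rep(1.5, 3)) # uniform map, edge-clipped too
  expect_false(any(v$excluded))

  ## disc inside a doubled nucleus reads close to 2
  centres <- data.frame(x = 32, y = 32)
  pre <- nucleiImage(64, centres, radiusPx = 8)
  post <- nucleiImage(64, centres, radiusPx = 8, nucleusLevel = 4)
  fm <- foldInductionMap(pre, post, umPerPx)
  v2 <- cellFoldInduction(fm$fold, centres, umPerPx, roiDiameterUm = 10)
  expect_equal(v2$fold_induction, 2, tolerance = 0.05)

  expect_error(cellFoldInduction(fold, data.frame(x = 100, y = 2), umPerPx),
               "outside")
})

test_that("decile grouping is exact, deterministic and monotone-invariant", {
  ## 10 distinct values: one per decile, top two are the high group
  v <- c(5, 1, 9, 3, 7, 2, 8, 4, 10, 6)
  g <- assignInductionGroups(v)
  expect_equal(g$decile, rank(v))
  expect_equal(sort(g$cell_id[g$group == "high"]), c(3, 9))
  expect_equal(sort(g$cell_id[g$group == "low"]), c(2, 6))

  ## 100 values: exactly 20 high and 20 low
  set.seed(9)
  v100 <- rlnorm(100)
  g100 <- assignInductionGroups(v100)
  expect_equal(sum(g100$group == "high"), 20)
  expect_equal(sum(g100$group == "low"), 20)

  ## invariant under strictly monotone transforms
  g2 <- assignInductionGroups(exp(v100))
  expect_equal(g100$decile, g2$decile)
  expect_equal(g100$group, g2$group)

  ## ties broken by cell id, deterministically
  vt <- rep(c(1, 2), each = 10)
  t1 <- assignInductionGroups(vt)
  t2 <- assignInductionGroups(vt)
  expect_identical(t1, t2)
  expect_equal(sum(t1$group == "high"), 4)

  ## degenerate all-equal input flagged
  gd <- assignInductionGroups(rep(1, 20))
  expect_true(attr(gd, "degenerate"))
  expect_error(assignInductionGroups(1:5), "at least 10")
})

test_that("time-course standardization removes gain drift and localizes induction in time", {
  set.seed(10)
  umPerPx <- 1
  centres <- data.frame(x = c(20, 50), y = c(40, 70))
  base <- nucleiImage(96, centres, radiusPx = 6) +
    matrix(runif(96 * 96, 0, 0.05), 96)

  ## pure multiplicative drift: per-cell fold stays at 1
  drift <- list(base, 1.4 * base, 0.7 * base, 2.1 * base)
  st <- standardizeTimecourse(drift, timesH = c(0, 1, 2, 3), centres,
                              umPerPx)
  expect_gt(st$A, 0)
  expect_true(all(abs(st$perCell - 1) < 0.05))

  ## doubled nuclei in the 3-h image show up in the 3-h bin only
  bright <- nucleiImage(96, centres, radiusPx = 6, nucleusLevel = 4) +
    matrix(runif(96 * 96, 0, 0.05), 96)
  series <- list(base, base, bright)
  st2 <- standardizeTimecourse(series, timesH = c(0, 1.2, 3.4), centres,
                               umPerPx)
  b1 <- st2$binned[st2$binned$hour_bin == 1, ]
  b3 <- st2$binned[st2$binned$hour_bin == 3, ]
  expect_true(all(b3$fold > 1.5))
  expect_true(all(abs(b1$fold - 1) < 0.1))

  expect_error(standardizeTimecourse(list(base), 0, centres, umPerPx),
               ">= 2")
})

test_that("16-bit TIFF images round-trip through disk", {
  set.seed(21)
  img <- matrix(sample(0:65535, 400), 20)
  f <- tempfile(fileext = ".tif")
  writeImageTiff(img, f)
  back <- readImageTiff(f)
  expect_equal(back, img)
  expect_error(writeImageTiff(matrix(-1), f), "0..65535")
  unlink(f)
})
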