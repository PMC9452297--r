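test_that("binned activity matches direct per-frame accumulation", {
  fr <- 30
  pos <- lapPosition(4, 8 * fr)
  set.seed(3)
  spd <- runif(length(pos), 0, 30) # some frames below the running threshold
  s <- toySession(pos, speed = spd,
                  licks = data.frame(frame = rep(seq(10, 230, 60), 4) +
                                       rep(c(0, 240, 480, 720), each = 4),
                                     kind = "test", trial = NA,
                                     position = NA))
  act <- matrix(rexp(3 * length(pos)), 3)
  elig <- eligibleTrials(s)
  got <- binActivity(s, act, elig)
  want <- oracleBinMeans(act, pos, spd, trialId(s), elig, 5, 40, 200)
  expect_equal(got$mean, want$mean)
  expect_equal(got$occupancy, want$occupancy)
  expect_equal(sum(got$occupancy), 1)

  ## constant activity gives a flat tuning curve at that constant
  gotC <- binActivity(s, matrix(2, 1, length(pos)), elig)
  expect_true(all(abs(gotC$mean - 2) < 1e-12, na.rm = TRUE))

  ## activity concentrated at position 7 cm lands in bin 1
  act1 <- matrix(0, 1, length(pos))
  act1[1, pos >= 6.5 & pos < 7.5] <- 5
  got1 <- binActivity(s, act1, elig)
  nz <- which(got1$mean[1, ] > 0) - 1L
  expect_equal(nz, 1L)
})

test_that("circular Gaussian smoothing preserves mass and wraps", {
  x <- rep(3, 40)
  expect_equal(smoothCircular(x), x)

  imp <- c(1, rep(0, 39))
  sm <- smoothCircular(imp)
  expect_equal(sum(sm), 1)
  expect_equal(sm[2], sm[40]) # symmetric wrap around bin 0
  expect_gt(sm[1], sm[2])
  ## matches the kernel itself, wrapped
  k <- exp(-pmin(0:39, 40 - (0:39))^2 / 2)
  expect_equal(sm, k / sum(k))

  ## NA bins are bridged from present neighbours
  y <- rep(1, 40)
  y[5] <- NA
  expect_equal(smoothCircular(y), rep(1, 40))
})

test_that("block shuffle index arithmetic matches an explicit construction", {
  ## 120 frames, offset 7, blocks reordered
  idx <- blockShuffleIndex(120, 7, c(3, 1, 6, 2, 5, 4))
  shifted <- ((seq_len(120) - 1 + 7) %% 120) + 1
  blocks <- split(shifted, rep(1:6, each = 20))
  expect_equal(idx, unname(unlist(blocks[c(3, 1, 6, 2, 5, 4)])))

  ## remainder goes to the leading blocks: 123 = 21+21+21+20+20+20
  idx2 <- blockShuffleIndex(123, 0, 1:6)
  sizes <- rle(rep(1:6, c(21, 21, 21, 20, 20, 20)))$lengths
  expect_equal(idx2, seq_len(123)) # identity order, shift 0
  expect_error(blockShuffleIndex(5, 0, 1:6), "fewer frames")

  ## a shuffle is a permutation of the frames
  expect_equal(sort(blockShuffleIndex(1000, 123, c(2, 4, 6, 1, 3, 5))),
               1:1000)
})

test_that("place-field calling follows the 3-consecutive-bin circular rule", {
  null <- rep(1, 40)
  ## 2 consecutive significant bins: no field
  x <- rep(0.5, 40)
  x[10:11] <- 2
  pf <- detectPlaceFields(x, null)
  expect_equal(nrow(pf$fields), 0)
  expect_false(pf$placeCell)

  ## all bins significant: one field covering the track
  pf <- detectPlaceFields(rep(2, 40), null)
  expect_equal(pf$fields$n_bins, 40)
  expect_equal(pf$fields$width_cm, 200)

  ## run wrapping bins 38,39,0,1 is one 4-bin field
  x <- rep(0.5, 40)
  x[c(39, 40, 1, 2)] <- 2
  pf <- detectPlaceFields(x, null)
  expect_equal(nrow(pf$fields), 1)
  expect_equal(pf$fields$n_bins, 4)
  expect_equal(pf$fields$start_bin, 38)

  ## ties are not significant (strict inequality)
  pf <- detectPlaceFields(rep(1, 40), null)
  expect_false(pf$placeCell)
})

test_that("spatial information matches closed forms and scales linearly", {
  ## flat tuning: H = 0
  expect_equal(spatialInformation(rep(2.5, 40), rep(1 / 40, 40)), 0)

  ## two bins, p = (1/2, 1/2), a = (2, 0): H = 1 bit
  expect_equal(spatialInformation(c(2, 0), c(0.5, 0.5)), 1)

  ## H(c * a) = c * H(a)
  set.seed(5)
  a <- rexp(40)
  p <- runif(40)
  p <- p / sum(p)
  H <- spatialInformation(a, p)
  expect_gt(H, 0)
  for (c in c(0.5, 3, 17)) {
    expect_equal(spatialInformation(c * a, p), c * H)
  }

  ## silent cell: defined as 0
  expect_equal(spatialInformation(rep(0, 40), rep(1 / 40, 40)), 0)
})

test_that("the shuffle null is flat for position-independent activity", {
  cfg <- simConfig(nTrials = 20, nCells = 10, pTuned = 0, seed = 19)
  b <- simulateSession(cfg)
  ses <- detectTransients(b$session)
  tun <- computeSpatialTuning(ses, nShuffles = 300, seed = 2)
  ## under the null, per-bin exceedance should be near the nominal 1%
  sig <- tun@smoothed > tun@nullCurve
  expect_lt(mean(sig, na.rm = TRUE), 0.05)
  ## H_norm distributes around 1 for untuned cells
  expect_lt(abs(median(tun@Hnorm, na.rm = TRUE) - 1), 0.5)
})

test_that("tuned cells are recovered with fields at the planted location", {
  cfg <- simConfig(nTrials = 40, nCells = 30, pTuned = 1,
                   reliability = c(0.85, 0.95), noiseSd = 0.05,
                   ensembleGainSd = 0, seed = 20)
  b <- simulateSession(cfg)
  ses <- detectTransients(b$session)
  tun <- computeSpatialTuning(ses, nShuffles = 300, seed = 3)
  expect_gt(mean(isPlaceCell(tun)), 0.9)
  ## detected peak within 2 bins of the planted centre (circularly)
  flds <- placeFields(tun)
  for (i in which(isPlaceCell(tun))) {
    peak <- flds$peak_bin[flds$cell == i][1]
    truthBin <- b$truth@cells$field_center_bin[i]
    d <- min(abs(peak - truthBin), 40 - abs(peak - truthBin))
    expect_lte(d, 2)
  }
})

test_that("single-shuffle percentile curve equals that shuffle", {
  cfg <- simConfig(nTrials = 10, nCells = 3, seed = 22)
  b <- simulateSession(cfg)
  ses <- detectTransients(b$session)
  sh <- shuffleNull(ses, nShuffles = 1, seed = 9)
  expect_equal(sh$nullCurve, sh$shuffleSmoothed[, , 1])
})

test_that("field properties match hand computation on a toy per-trial matrix", {
  cfg <- simConfig(nTrials = 12, nCells = 8, pTuned = 1,
                   reliability = c(1, 1), noiseSd = 0.05,
                   ensembleGainSd = 0, seed = 23)
  b <- simulateSession(cfg)
  ses <- detectTransients(b$session)
  tun <- computeSpatialTuning(ses, nShuffles = 200, seed = 4)
  cell <- which(isPlaceCell(tun))[1]
  fp <- fieldProperties(tun, ses, cell)
  ## perfectly reliable cells fire their field on every trial
  expect_equal(fp$fractionActive, 1)
  expect_gt(fp$selectivity, 0.8)
  expect_gt(fp$trialToTrialCorr, 0.5)

  ## hand-check the off-diagonal mean on the cell's own per-trial matrix
  perTrial <- tun@perTrial[, , cell]
  n <- nrow(perTrial)
  cc <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(perTrial[i, ]) & !is.na(perTrial[j, ])
    ai <- perTrial[i, ok]; aj <- perTrial[j, ok]
    hasI <- any(!is.na(perTrial[i, ]) & perTrial[i, ] > 0)
    hasJ <- any(!is.na(perTrial[j, ]) & perTrial[j, ] > 0)
    r <- if (hasI && hasJ && sd(ai) > 0 && sd(aj) > 0) cor(ai, aj) else 0
    cc[i, j] <- r
  }
  expect_equal(fp$trialToTrialCorr, mean(cc[upper.tri(cc)]))

  if (any(!isPlaceCell(tun)))
    expect_error(fieldProperties(tun, ses, which(!isPlaceCell(tun))[1]),
                 "no place field")
})
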