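test_that("per-cell tuning correlations behave on identity, shift and toy cases", {
  set.seed(16)
  ref <- matrix(rexp(5 * 40), 5)
  expect_equal(placefieldCorrelation(ref, ref), rep(1, 5))

  ## unimodal field shifted to the antipode anticorrelates
  curve <- exp(-(((0:39) - 10)^2) / 8)
  shifted <- curve[((0:39) - 20) %% 40 + 1]
  x <- placefieldCorrelation(matrix(curve, 1), matrix(shifted, 1))
  expect_lt(x, 0)

  ## 4-bin toy case against a hand-computed value
  a <- c(1, 2, 3, 4)
  b <- c(2, 1, 4, 3)
  expect_equal(placefieldCorrelation(matrix(a, 1), matrix(b, 1)),
               cor(a, b))

  ## zero-variance rows are skipped
  z <- placefieldCorrelation(matrix(1, 1, 40), matrix(rexp(40), 1))
  expect_true(is.na(z))
})

test_that("stability maps are activity-weighted means of x", {
  nBins <- 40
  ## identity comparison: map is 1 wherever any cell has weight
  set.seed(17)
  ref <- matrix(rexp(25 * nBins), 25)
  sm <- stabilityMap(rep(1, 25), ref, minCells = 20)
  expect_true(all(abs(sm@stability - 1) < 1e-12, na.rm = TRUE))

  ## two disjoint single-bin cells carry their own x to their own bin
  ref2 <- matrix(0, 2, nBins)
  ref2[1, 5] <- 3
  ref2[2, 30] <- 7
  sm2 <- stabilityMap(c(1, -1), ref2, minCells = 2)
  expect_equal(sm2@stability[5], 1)
  expect_equal(sm2@stability[30], -1)
  expect_true(all(is.na(sm2@stability[-c(5, 30)])))

  ## random instance equals a double-loop weighted-mean oracle
  x <- runif(25, -1, 1)
  smr <- stabilityMap(x, ref, minCells = 20)
  w <- ref / rowSums(ref)
  oracle <- vapply(seq_len(nBins), function(b) {
    num <- 0; den <- 0
    for (c in 1:25) {
      num <- num + w[c, b] * x[c]
      den <- den + w[c, b]
    }
    num / den
  }, numeric(1))
  expect_equal(smr@stability, oracle)

  ## invariant to per-cell rescaling of the reference activity
  smScaled <- stabilityMap(x, ref * runif(25, 0.1, 10), minCells = 20)
  expect_equal(smScaled@stability, smr@stability)

  ## the minimum-cell rule excludes small groups
  expect_error(stabilityMap(rep(1, 5), ref[1:5, ]), "excluded")
})

test_that("zone summaries average the configured peri-reward and no-reward bins", {
  rz <- c(100, 120)
  stab <- rep(0.5, 40)
  zs <- zoneSummary(stab, rz)
  expect_equal(unname(zs), c(0.5, 0.5))

  ## peri-reward = reward zone +/- 20 cm = 80-140 cm = bins 16..27
  stab2 <- rep(0, 40)
  stab2[17:28] <- 1
  zs2 <- zoneSummary(stab2, rz)
  expect_equal(unname(zs2), c(1, 0))

  set.seed(18)
  stab3 <- runif(40)
  zs3 <- zoneSummary(stab3, rz)
  expect_equal(unname(zs3[1]), mean(stab3[17:28]))
  expect_equal(unname(zs3[2]), mean(stab3[-(17:28)]))
  expect_error(zoneSummary(stab3, rz, zones = list(a = integer(0), b = 1:3)),
               "empty")
})

test_that("sign-flip permutation test matches exhaustive enumeration on a small case", {
  set.seed(19)
  ## identical groups: p near 1 everywhere
  A <- matrix(runif(4 * 40), 4)
  r <- stabilityDifferenceTest(A, A, c(100, 120), nShuffles = 200, seed = 1)
  expect_true(all(r$perBinP > 0.9))

  ## constant offset: per-bin p at the smoothing floor
  B <- A + 0.4
  r2 <- stabilityDifferenceTest(B, A, c(100, 120), nShuffles = 200, seed = 1)
  ## only 2^4 = 16 distinct sign patterns; all-keep and all-flip tie |obs|
  expect_true(all(r2$perBinP < 0.2))

  ## exhaustive 2^4 oracle on the zone contrast
  D <- B - A + matrix(rnorm(160, 0, 0.05), 4)
  mapsA <- A + D
  zones <- list(peri = 16:27, rest = setdiff(0:39, 16:27))
  zstat <- function(Dm) {
    bd <- colMeans(Dm)
    mean(bd[zones$peri + 1]) - mean(bd[zones$rest + 1])
  }
  obs <- zstat(D)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  nullStats <- apply(flips, 1, function(f) zstat(D * f))
  pExact <- mean(abs(nullStats) >= abs(obs) - 1e-12)
  r3 <- stabilityDifferenceTest(mapsA, A, c(100, 120), zones = zones,
                                nShuffles = 4000, seed = 2)
  expect_equal(r3$zoneContrast, obs)
  expect_equal(r3$zoneContrastP, pExact, tolerance = 0.05)

  expect_error(stabilityDifferenceTest(A[1, , drop = FALSE],
                                       A[1, , drop = FALSE], c(100, 120)),
               "at least 2")
})

test_that("remapping contingency recovers planted induction coupling", {
  set.seed(20)
  n <- 400
  fieldE1 <- rep(c(TRUE, FALSE), each = n / 2)
  gained <- !fieldE1 & runif(n) < 0.5
  lost <- fieldE1 & runif(n) < 0.5
  fieldE2 <- (fieldE1 & !lost) | gained

  ## induction independent of transitions: ratios near 1
  highRnd <- runif(n) < 0.3
  rc <- remapContingency(fieldE1, fieldE2, highRnd, nPerm = 300, seed = 1)
  expect_equal(rc$ratio, c(1, 1), tolerance = 0.45)
  expect_true(all(rc$p_value > 0.01))

  ## cells that gained a field are always high: maximal enrichment
  highCpl <- gained
  rcC <- remapContingency(fieldE1, fieldE2, highCpl, nPerm = 300, seed = 2)
  g <- rcC[rcC$transition == "gained", ]
  expect_equal(g$p_high_given_event, 1)
  expect_equal(g$p_high_given_none, 0)
  expect_lt(g$p_value, 0.01)

  ## toy counts follow hand arithmetic
  f1 <- rep(c(TRUE, FALSE), c(4, 6))
  f2 <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  hi <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  rcT <- remapContingency(f1, f2, hi, nPerm = 50, seed = 3)
  gT <- rcT[rcT$transition == "gained", ]
  expect_equal(gT$p_high_given_event, 2 / 3) # gained: cells 5,6,7 -> 2 high
  expect_equal(gT$p_high_given_none, 1 / 3)  # not gained: 8,9,10 -> 1 high
  lT <- rcT[rcT$transition == "lost", ]
  expect_equal(lT$p_high_given_event, 1 / 2) # lost: 3,4 -> 1 high
  expect_equal(lT$p_high_given_none, 1 / 2)  # kept: 1,2 -> 1 high
})

test_that("planted stability differences are recovered end to end on a session pair", {
  cfg <- simConfig(nCells = 120, nTrials = 30, pTuned = 1, nSessions = 2,
                   reliability = c(0.9, 0.95),
                   tuningStabilityRho = c(0.35, 0.95), missingFraction = 0,
                   ensembleGainSd = 0, seed = 28)
  ms <- simulateMultiSession(cfg)
  tun <- lapply(1:2, function(s) {
    ses <- detectTransients(ms$sessions[[s]]$session)
    computeSpatialTuning(ses, nShuffles = 150, seed = s)
  })
  rel <- ms$truths[[1]]@cells$reliability_p
  rho <- ms$truths[[1]]@cells$stability_rho
  hiRho <- which(rho > median(rho))
  loRho <- which(rho <= median(rho))
  ref <- tuningCurves(tun[[1]])
  tgt <- tuningCurves(tun[[2]])
  x <- placefieldCorrelation(ref, tgt)
  smHi <- stabilityMap(x[hiRho], ref[hiRho, ], minCells = 20)
  smLo <- stabilityMap(x[loRho], ref[loRho, ], minCells = 20)
  expect_gt(mean(smHi@stability, na.rm = TRUE),
            mean(smLo@stability, na.rm = TRUE))
})
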