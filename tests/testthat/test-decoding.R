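## A small fully-visited session for template fitting: constant-speed laps
## with enough licks that every trial is eligible.
eligibleLapSession <- function(nLaps = 4, secPerLap = 8, fr = 30,
                               nCells = 0, dff = NULL) {
  pos <- lapPosition(nLaps, secPerLap * fr)
  nFrames <- length(pos)
  perLap <- secPerLap * fr
  licks <- data.frame(frame = rep(seq(10, perLap - 10, length.out = 4),
                                  nLaps) +
                        rep((seq_len(nLaps) - 1) * perLap, each = 4),
                      kind = "test", trial = NA, position = NA)
  toySession(pos, speed = rep(25, nFrames), licks = licks, dff = dff)
}

test_that("trials split into odd testing and even training over eligible trials", {
  sp <- trainTestSplit(c(3, 5, 8, 9, 12))
  expect_equal(sp$train, c(5, 9))
  expect_equal(sp$test, c(3, 8, 12))
})

test_that("templates average training-trial binned activity and floor at epsilon", {
  s <- eligibleLapSession(4)
  nF <- length(position(s))
  act <- matrix(0, 2, nF)
  tid <- trialId(s)
  pos <- position(s)
  ## cell 1 active at 50 cm on trial 2 with value 3, on trial 4 with value 1
  act[1, tid == 2 & pos >= 50 & pos < 55] <- 3
  act[1, tid == 4 & pos >= 50 & pos < 55] <- 1
  tm <- fitTemplates(s, act, trainTrials = c(2, 4))
  expect_equal(tm@templates[1, 11], 2) # hand mean of the two trials
  expect_true(all(tm@templates >= tm@epsilon))

  ## a single training trial reproduces that trial's binned activity
  tm1 <- fitTemplates(s, act, trainTrials = 2)
  expect_equal(tm1@templates[1, 11], 3)
})

test_that("frame decoding matches the product-form posterior", {
  s <- eligibleLapSession(2)
  nF <- length(position(s))

  ## one cell, templates (2, 1) over two bins: hand-evaluated posterior
  tm <- new("TemplateSet",
            templates = matrix(c(2, 1), 1), tau = 1 / 30, epsilon = 0.01,
            trainTrials = 1L, validBins = c(TRUE, TRUE))
  d <- decodeFrame(tm, 5)
  ## P(bin) ~ f^a * exp(-tau f): 32 e^{-2/30} vs 1 e^{-1/30}
  w <- c(2^5 * exp(-2 / 30), 1^5 * exp(-1 / 30))
  expect_equal(d$posterior, w / sum(w))
  expect_equal(d$decodedBin, 0L)

  ## identical templates: uniform posterior, tie broken to bin 0
  tmU <- new("TemplateSet", templates = matrix(1, 3, 5), tau = 1 / 30,
             epsilon = 0.01, trainTrials = 1L, validBins = rep(TRUE, 5))
  dU <- decodeFrame(tmU, c(1, 2, 0))
  expect_equal(dU$posterior, rep(0.2, 5))
  expect_equal(dU$decodedBin, 0L)

  ## random instances agree with a linear-domain (no-log) oracle
  set.seed(6)
  for (r in 1:20) {
    f <- matrix(runif(4 * 8, 0.05, 3), 4)
    tmR <- new("TemplateSet", templates = f, tau = 1 / 30, epsilon = 0.05,
               trainTrials = 1L, validBins = rep(TRUE, 8))
    a <- rexp(4)
    d <- decodeFrame(tmR, a)
    lin <- apply(f, 2, function(col) prod(col^a)) *
      exp(-colSums(f) / 30)
    expect_equal(d$posterior, lin / sum(lin))
    expect_equal(d$decodedBin, which.max(lin) - 1L)
    expect_equal(sum(d$posterior), 1)
  }
})

test_that("circular decoding error never exceeds half the track", {
  cfg <- simConfig(nTrials = 16, nCells = 25, seed = 24)
  b <- simulateSession(cfg)
  ses <- detectTransients(b$session)
  tm <- fitTemplates(ses)
  dr <- decodeSession(tm, ses)
  expect_true(all(dr@errorCm >= 0 & dr@errorCm <= 100))
  ## antipodal and wrap-around hand cases for the error metric
  expect_equal(fosplace:::.circDistCm(2.5, 102.5, 200), 100)
  expect_equal(fosplace:::.circDistCm(10, 190, 200), 20)
})

test_that("a noiseless reliable population decodes to within one bin", {
  cfg <- simConfig(nCells = 100, pTuned = 1, reliability = c(1, 1),
                   noiseSd = 0, ensembleGainSd = 0, seed = 5)
  b <- simulateSession(cfg)
  act <- dff(b$session)
  tm <- fitTemplates(b$session, activity = act)
  dr <- decodeSession(tm, b$session, activity = act)
  expect_lt(dr@meanError, 5)
})

test_that("group comparison subsamples to matched sizes with shared frames", {
  cfg <- simConfig(nTrials = 24, nCells = 40, pTuned = 1, seed = 26)
  b <- simulateSession(cfg)
  ses <- detectTransients(b$session)
  ## two identical groups: equal errors within resampling noise
  g <- list(a = 1:20, b = 1:20)
  err <- compareGroupsDecoding(ses, g, nReps = 10, seed = 1)
  expect_equal(err[["a"]], err[["b"]], tolerance = 0.15)

  ## smaller group below the floor excludes the session
  expect_error(compareGroupsDecoding(ses, list(a = 1:9, b = 10:40)),
               "excluded")
})

test_that("reliable populations decode better than unreliable ones", {
  cfg <- simConfig(nTrials = 30, nCells = 60, pTuned = 1,
                   reliability = c(0.25, 0.95), ensembleGainSd = 0,
                   seed = 27)
  b <- simulateSession(cfg)
  ses <- detectTransients(b$session)
  rel <- b$truth@cells$reliability_p
  groups <- list(reliable = order(rel, decreasing = TRUE)[1:15],
                 unreliable = order(rel)[1:15])
  err <- compareGroupsDecoding(ses, groups, nReps = 15, seed = 2)
  expect_lt(err[["reliable"]], err[["unreliable"]])
})

test_that("activity matching balances mean alpha within log bins", {
  set.seed(7)
  alpha <- c(rlnorm(100, 1, 0.6), rlnorm(100, 0.3, 0.6))
  hi <- 1:100
  lo <- 101:200
  pre <- abs(mean(alpha[hi]) - mean(alpha[lo]))
  m <- activityMatch(alpha, hi, lo, seed = 1)
  expect_equal(length(m$high), length(m$low))
  post <- abs(mean(alpha[m$high]) - mean(alpha[m$low]))
  expect_lt(post, 0.1 * pre)

  ## identical alpha multisets: everything is retained
  alpha2 <- rep(rlnorm(30, 0, 0.5), 2)
  m2 <- activityMatch(alpha2, 1:30, 31:60, seed = 2)
  expect_equal(length(m2$high), 30)
  expect_equal(sort(m2$high), 1:30)
  expect_equal(sort(m2$low), 31:60)

  ## a bin where one group is absent contributes nothing
  alpha3 <- c(rep(1, 5), rep(1000, 5), rep(1, 5))
  m3 <- activityMatch(alpha3, 1:10, 11:15, seed = 3)
  expect_true(all(alpha3[m3$high] == 1))
  expect_equal(length(m3$high), 5)
})
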