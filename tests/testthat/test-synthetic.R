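test_that("behaviour generation is deterministic and geometrically valid", {
  cfg <- simConfig(nTrials = 15, nCells = 4, seed = 8)
  s1 <- simulateBehavior(cfg)
  s2 <- simulateBehavior(cfg)
  expect_identical(position(s1), position(s2))
  expect_identical(licks(s1), licks(s2))
  expect_identical(rewards(s1), rewards(s2))

  expect_true(all(position(s1) >= 0 & position(s1) < 200))
  expect_true(all(speed(s1) >= 0))
  expect_false(is.unsorted(trialId(s1)))
  expect_equal(max(trialId(s1)), 15)

  ## full simulated bundles are bit-identical under the same seed
  b1 <- simulateSession(cfg)
  b2 <- simulateSession(cfg)
  expect_identical(dff(b1$session), dff(b2$session))
  expect_identical(b1$induction, b2$induction)
})

test_that("trial-type fractions match the configuration at large n", {
  cfg <- simConfig(nTrials = 400, nCells = 1, seed = 10)
  s <- simulateBehavior(cfg)
  frac <- table(factor(trials(s)$type,
                       c("standard", "crutch", "probe"))) / 400
  expect_equal(as.numeric(frac), c(0.65, 0.25, 0.10), tolerance = 0.35)
  ## multinomial 3-sigma bounds
  p <- c(0.65, 0.25, 0.10)
  expect_true(all(abs(as.numeric(frac) - p) < 3 * sqrt(p * (1 - p) / 400)))
})

test_that("trace generation obeys the reliability model", {
  ## reliability 1, no noise: every trial shows one in-field transient
  cfg <- simConfig(nTrials = 10, nCells = 6, pTuned = 1,
                   reliability = c(1, 1), noiseSd = 0, ensembleGainSd = 0,
                   seed = 12)
  b <- simulateSession(cfg)
  mat <- dff(b$session)
  tid <- trialId(b$session)
  for (i in 1:6) {
    perTrial <- vapply(1:10, function(t) max(mat[i, tid == t]), numeric(1))
    expect_true(all(perTrial > 0.5 * b$truth@cells$amplitude[i]))
  }

  ## reliability 0: tuned cells emit nothing, trace is pure noise
  cfg0 <- simConfig(nTrials = 10, nCells = 6, pTuned = 1,
                    reliability = c(0, 0), noiseSd = 0.1, seed = 12)
  b0 <- simulateSession(cfg0)
  expect_false(any(b0$truth@eventMask))
  expect_lt(max(abs(dff(b0$session))), 1) # noise-only scale

  ## reliability 0.5 over 100 trials: event fraction within binomial error
  cfg5 <- simConfig(nTrials = 100, nCells = 20, pTuned = 1,
                    reliability = c(0.5, 0.5), seed = 13)
  b5 <- simulateSession(cfg5)
  ev <- b5$truth@sessions
  frac <- mean(ev$event)
  se <- sqrt(0.25 / (100 * 20))
  expect_lt(abs(frac - 0.5), 4 * se)
})

test_that("induction tracks integrated activity as configured", {
  cfg <- simConfig(nTrials = 20, nCells = 40, seed = 14)
  b <- simulateSession(cfg)
  act <- rowSums(dff(b$session))

  ## gain 0: no association
  cfg0 <- simConfig(nTrials = 20, nCells = 40, inductionGain = 0, seed = 14)
  b0 <- simulateSession(cfg0)
  r0 <- suppressWarnings(cor(rowSums(dff(b0$session)),
                             b0$induction$fold_induction,
                             method = "spearman"))
  expect_lt(abs(r0), 0.4)

  ## no noise, positive gain: rank order preserved exactly
  cfgE <- simConfig(nTrials = 20, nCells = 40, inductionNoiseSd = 0,
                    seed = 14)
  bE <- simulateSession(cfgE)
  expect_equal(order(bE$induction$fold_induction),
               order(rowSums(dff(bE$session))))

  ## noisy positive gain: positive rank correlation
  r <- cor(act, b$induction$fold_induction, method = "spearman")
  expect_gt(r, 0.5)
  expect_true(all(b$induction$fold_induction > 0))
})

test_that("multi-day generation controls field persistence", {
  ## rho = 1: identical ground-truth tuning in all sessions
  cfg1 <- simConfig(nCells = 30, nTrials = 8, nSessions = 3,
                    tuningStabilityRho = c(1, 1), missingFraction = 0,
                    seed = 15)
  ms <- simulateMultiSession(cfg1)
  f1 <- ms$truths[[1]]@cells$field_center_bin
  expect_identical(f1, ms$truths[[2]]@cells$field_center_bin)
  expect_identical(f1, ms$truths[[3]]@cells$field_center_bin)

  ## rho = 0, remap 1: every tuned cell redraws its field each step
  cfg0 <- simConfig(nCells = 200, nTrials = 8, nSessions = 2, pTuned = 1,
                    tuningStabilityRho = c(0, 0), remapFraction = 1,
                    missingFraction = 0, seed = 16)
  ms0 <- simulateMultiSession(cfg0)
  same <- ms0$truths[[1]]@cells$field_center_bin ==
    ms0$truths[[2]]@cells$field_center_bin
  expect_lt(mean(same), 0.1) # 1/40 chance collisions only

  ## rho = 0.8 on 1000 cells: persistence within binomial error
  cfg8 <- simConfig(nCells = 1000, nTrials = 4, nSessions = 2, pTuned = 1,
                    tuningStabilityRho = c(0.8, 0.8), missingFraction = 0,
                    seed = 17)
  ms8 <- simulateMultiSession(cfg8)
  kept <- mean(ms8$persistence[, 2])
  expect_lt(abs(kept - 0.8), 4 * sqrt(0.8 * 0.2 / 1000))

  ## alignment covers present cells only and maps ids consistently
  cfgA <- simConfig(nCells = 50, nTrials = 4, nSessions = 2,
                    missingFraction = 0.2, seed = 18)
  msA <- simulateMultiSession(cfgA)
  al <- msA$alignment
  expect_equal(sum(al$session == 1), 50)
  n2 <- sum(al$session == 2)
  expect_lt(n2, 50)
  expect_equal(nrow(msA$truths[[2]]@cells), n2)
})

test_that("config validation rejects inconsistent geometry", {
  expect_error(simConfig(rewardZone = c(150, 250)), "rewardZone")
  expect_error(simConfig(nTrials = 0), "trial")
  expect_error(simConfig(trialTypeFractions = c(0.5, 0.2, 0.1)),
               "summing to 1")
  expect_error(simConfig(reliability = c(0.5, 1.5)), "probabilities")
})
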