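## Synthetic virtual-track data generator. Emulates the statistical structure
## the downstream analyses assume: lap-structured behaviour at 30 Hz with
## standard/crutch/probe trials, place-tuned calcium transients with known
## per-cell field centre, width, amplitude and trial-to-trial reliability,
## fold-induction values coupled to integrated activity, and multi-day
## session sets with controlled field persistence and remapping.

#' Build a simulation configuration
#'
#' Defaults follow the task geometry of the virtual-track experiment: a
#' 200-cm circular track divided into 40 bins of 5 cm, a 20-cm reward zone
#' (one tenth of the track), 30-Hz frames, and standard/crutch/probe trials
#' at 65/25/10%.
#'
#' @param trackLengthCm,nBins,frameRateHz,rewardZone,nTrials,trialTypeFractions,nCells,pTuned,fieldWidthCm,amplitude,reliability,eventDecayS,noiseSd,inductionBaseline,inductionGain,inductionNoiseSd,speedMeanCmS,speedSdLog,rewardZoneSlowFactor,lickPolicy,licksPerTrial,rewardVolumeMl,nSessions,tuningStabilityRho,remapFraction,missingFraction,ensembleGainSd,seed see [SimConfig-class].
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(trackLengthCm = 200, nBins = 40, frameRateHz = 30,
                      rewardZone = c(100, 120), nTrials = 40,
                      trialTypeFractions = c(standard = 0.65, crutch = 0.25,
                                             probe = 0.10),
                      nCells = 60, pTuned = 0.7,
                      fieldWidthCm = c(15, 35), amplitude = c(1.5, 3),
                      reliability = c(0.3, 0.9), eventDecayS = 0.5,
                      noiseSd = 0.1, inductionBaseline = 1,
                      inductionGain = 0.3, inductionNoiseSd = 0.1,
                      speedMeanCmS = 25, speedSdLog = 0.25,
                      rewardZoneSlowFactor = 0.5, lickPolicy = "expert",
                      licksPerTrial = 8, rewardVolumeMl = 0.004,
                      nSessions = 1, tuningStabilityRho = c(0.5, 0.95),
                      remapFraction = 0.3, missingFraction = 0.1,
                      ensembleGainSd = 0.5, seed = 1) {
  if (length(reliability) == 1) reliability <- rep(reliability, 2)
  if (length(tuningStabilityRho) == 1)
    tuningStabilityRho <- rep(tuningStabilityRho, 2)
  if (length(fieldWidthCm) == 1) fieldWidthCm <- rep(fieldWidthCm, 2)
  if (length(amplitude) == 1) amplitude <- rep(amplitude, 2)
  new("SimConfig", trackLengthCm = trackLengthCm, nBins = as.integer(nBins),
      frameRateHz = frameRateHz, rewardZone = rewardZone,
      nTrials = as.integer(nTrials),
      trialTypeFractions = trialTypeFractions, nCells = as.integer(nCells),
      pTuned = pTuned, fieldWidthCm = fieldWidthCm, amplitude = amplitude,
      reliability = reliability, eventDecayS = eventDecayS, noiseSd = noiseSd,
      inductionBaseline = inductionBaseline, inductionGain = inductionGain,
      inductionNoiseSd = inductionNoiseSd, speedMeanCmS = speedMeanCmS,
      speedSdLog = speedSdLog, rewardZoneSlowFactor = rewardZoneSlowFactor,
      lickPolicy = lickPolicy, licksPerTrial = licksPerTrial,
      rewardVolumeMl = rewardVolumeMl, nSessions = as.integer(nSessions),
      tuningStabilityRho = tuningStabilityRho, remapFraction = remapFraction,
      missingFraction = missingFraction, ensembleGainSd = ensembleGainSd,
      seed = as.integer(seed))
}

#' Draw per-cell ground truth
#'
#' Tuned cells (probability `pTuned`) get one field with a uniform centre
#' bin, a width and amplitude uniform in their configured ranges, and a
#' trial-to-trial reliability uniform in `reliability`. The intended
#' induction group tiers cells by reliability (top 20% "high", bottom 20%
#' "low") and each cell's day-to-day persistence probability interpolates
#' `tuningStabilityRho` over its reliability, so high-induction cells are
#' also the more stable ones.
#'
#' @param config a [SimConfig-class].
#' @param seed RNG seed (defaults to the config seed).
#' @return a [GroundTruth-class].
#' @export
simulateGroundTruth <- function(config, seed = config@seed) {
  validObject(config)
  set.seed(.substreamSeed(seed, "truth"))
  n <- config@nCells
  tuned <- runif(n) < config@pTuned
  rel <- runif(n, config@reliability[1], config@reliability[2])
  width <- runif(n, config@fieldWidthCm[1], config@fieldWidthCm[2])
  amp <- runif(n, config@amplitude[1], config@amplitude[2])
  centre <- sample.int(config@nBins, n, replace = TRUE) - 1L
  binSize <- config@trackLengthCm / config@nBins
  rr <- config@reliability
  relScale <- if (rr[2] > rr[1]) (rel - rr[1]) / (rr[2] - rr[1]) else
    rep(0.5, n)
  rho <- config@tuningStabilityRho[1] +
    relScale * diff(config@tuningStabilityRho)
  q <- rank(rel, ties.method = "first")
  group <- rep("mid", n)
  group[q > 0.8 * n] <- "high"
  group[q <= 0.2 * n] <- "low"
  cells <- data.frame(
    cell_id = seq_len(n), is_tuned = tuned,
    field_center_bin = ifelse(tuned, centre, NA_integer_),
    field_width_bins = ifelse(tuned, pmax(1, round(width / binSize)), NA),
    field_width_cm = ifelse(tuned, width, NA),
    reliability_p = rel, amplitude = amp, stability_rho = rho, group = group)
  new("GroundTruth", cells = cells, eventMask = matrix(FALSE, 0, 0),
      sessions = data.frame(), config = config)
}

#' Simulate one session of behaviour
#'
#' Laps on the circular track with a piecewise-constant per-trial running
#' speed drawn from a lognormal, slowed by `rewardZoneSlowFactor` inside the
#' reward zone. Trial types are drawn from `trialTypeFractions`. The "expert"
#' lick policy concentrates test licks in the 10 cm before the reward zone
#' and inside it (with at least one lick in each on every trial); the
#' "novice" policy licks uniformly along the track. Rewards follow the
#' trial-type rule: standard trials reward the first lick inside the zone,
#' crutch trials reward zone entry, probe trials are never rewarded.
#' Consumption licks (in-zone, post-reward) are appended and classified by
#' [annotateTrials()], which also computes eligibility.
#'
#' @param config a [SimConfig-class].
#' @param seed RNG seed.
#' @return an annotated [CalciumSession-class] without traces.
#' @export
simulateBehavior <- function(config, seed = config@seed) {
  validObject(config)
  set.seed(.substreamSeed(seed, "behavior"))
  tl <- config@trackLengthCm
  fr <- config@frameRateHz
  rz <- config@rewardZone
  dt <- 1 / fr
  nT <- config@nTrials
  types <- sample(c("standard", "crutch", "probe"), nT, replace = TRUE,
                  prob = config@trialTypeFractions)

  posL <- spdL <- vector("list", nT)
  trialStart <- integer(nT)
  frame0 <- 0L
  for (t in seq_len(nT)) {
    vBase <- rlnorm(1, log(config@speedMeanCmS) - config@speedSdLog^2 / 2,
                    config@speedSdLog)
    p <- numeric(0)
    v <- numeric(0)
    cur <- 0
    while (cur < tl) {
      sp <- vBase * if (cur >= rz[1] && cur < rz[2])
        config@rewardZoneSlowFactor else 1
      p <- c(p, cur)
      v <- c(v, sp)
      cur <- cur + sp * dt
    }
    posL[[t]] <- p
    spdL[[t]] <- v
    trialStart[t] <- frame0 + 1L
    frame0 <- frame0 + length(p)
  }
  pos <- unlist(posL)
  spd <- unlist(spdL)
  tid <- rep(seq_len(nT), lengths(posL))
  nFrames <- length(pos)

  ## licks specified by position, mapped to the first frame of the trial at or
  ## past that position
  lickFrame <- function(t, lickPos) {
    idx <- which(tid == t & pos >= lickPos)
    if (length(idx)) idx[1] else NA_integer_
  }
  lickRows <- list()
  rewardRows <- list()
  for (t in seq_len(nT)) {
    if (config@lickPolicy == "expert") {
      nPre <- 1L + rpois(1, config@licksPerTrial / 3)
      nZone <- 1L + rpois(1, config@licksPerTrial / 3)
      lickPos <- c(runif(nPre, rz[1] - 10, rz[1]), runif(nZone, rz[1], rz[2]))
    } else {
      nLick <- 1L + rpois(1, config@licksPerTrial)
      lickPos <- runif(nLick, 0, tl)
    }
    lickPos <- sort(lickPos %% tl)
    frames <- vapply(lickPos, function(p) lickFrame(t, p), integer(1))
    keep <- !is.na(frames)
    lickPos <- lickPos[keep]; frames <- frames[keep]

    ## reward per trial-type rule
    rewFrame <- NA_integer_
    if (types[t] == "standard") {
      zoneLick <- frames[lickPos >= rz[1] & lickPos < rz[2]]
      if (length(zoneLick)) rewFrame <- zoneLick[1]
    } else if (types[t] == "crutch") {
      entry <- which(tid == t & pos >= rz[1])
      if (length(entry)) rewFrame <- entry[1]
    }
    if (!is.na(rewFrame))
      rewardRows[[length(rewardRows) + 1L]] <-
        data.frame(frame = rewFrame, volume = config@rewardVolumeMl,
                   manual = FALSE, trial = t)

    ## consumption licks after reward while still inside the zone
    if (!is.na(rewFrame)) {
      zoneAfter <- which(tid == t & pos >= rz[1] & pos < rz[2] &
                         seq_len(nFrames) > rewFrame)
      nCons <- min(length(zoneAfter), rpois(1, 3))
      if (nCons > 0) {
        cf <- sort(sample(zoneAfter, nCons))
        frames <- c(frames, cf)
        lickPos <- c(lickPos, pos[cf])
      }
    }
    if (length(frames))
      lickRows[[length(lickRows) + 1L]] <-
        data.frame(frame = frames, kind = "test", trial = t,
                   position = lickPos)
  }
  lk <- if (length(lickRows)) do.call(rbind, lickRows) else .emptyLicks()
  lk <- lk[order(lk$frame), , drop = FALSE]
  rownames(lk) <- NULL
  rw <- if (length(rewardRows)) do.call(rbind, rewardRows) else
    .emptyRewards()

  x <- CalciumSession(position = pos, speed = spd, trialId = tid,
                      frameRate = fr, trackLength = tl, rewardZone = rz,
                      licks = lk, rewards = rw,
                      trials = data.frame(type = types))
  annotateTrials(x, trialTypes = types)
}

#' Simulate calcium dF/F traces for a session
#'
#' For each tuned cell, each trial carries an event with probability
#' `reliability_p`: the drive is the amplitude times a Gaussian spatial
#' envelope around the field centre (s.d. = field width / 4), evaluated on
#' the trajectory, and is convolved with a unit-sum single-exponential decay
#' kernel (`eventDecayS`). Untuned cells emit position-independent
#' Poisson-timed impulse events at `untunedRateHz`. Zero-mean Gaussian noise
#' of s.d. `noiseSd` is added. The noiseless per-frame event mask (event
#' extent at half maximum, i.e. signal above half the cell's amplitude) and
#' the per-trial event draws are stored in the returned [GroundTruth-class].
#'
#' @param session an annotated behaviour session.
#' @param truth a [GroundTruth-class] (from [simulateGroundTruth()]).
#' @param config a [SimConfig-class].
#' @param seed RNG seed.
#' @param untunedRateHz event rate of untuned cells.
#' @return list with elements `session` (dff assay filled) and `truth`
#'   (eventMask and per-trial event table filled).
#' @export
simulateTraces <- function(session, truth, config, seed = config@seed,
                           untunedRateHz = 0.03) {
  stopifnot(is(session, "CalciumSession"), is(truth, "GroundTruth"))
  set.seed(.substreamSeed(seed, "traces"))
  pos <- position(session)
  tid <- trialId(session)
  nFrames <- length(pos)
  nT <- max(tid)
  fr <- frameRate(session)
  tl <- trackLength(session)
  binSize <- tl / config@nBins
  cells <- truth@cells
  n <- nrow(cells)

  tau <- config@eventDecayS * fr
  kLen <- ceiling(5 * tau)
  kernel <- exp(-(0:kLen) / tau)
  kernel <- kernel / sum(kernel)

  ## shared per-trial gain planting ensemble co-fluctuation in the high tier
  trialGain <- if (config@ensembleGainSd > 0)
    rlnorm(nT, 0, config@ensembleGainSd) else rep(1, nT)

  mat <- matrix(0, n, nFrames)
  mask <- matrix(FALSE, n, nFrames)
  trialEvent <- matrix(FALSE, n, nT)
  convDecay <- function(drive) {
    s <- stats::filter(c(numeric(kLen), drive), kernel,
                       method = "convolution", sides = 1)
    as.numeric(s)[kLen + seq_len(nFrames)]
  }
  for (i in seq_len(n)) {
    amp <- cells$amplitude[i]
    if (cells$is_tuned[i]) {
      centreCm <- (cells$field_center_bin[i] + 0.5) * binSize
      sigmaCm <- cells$field_width_cm[i] / 4
      fire <- runif(nT) < cells$reliability_p[i]
      trialEvent[i, ] <- fire
      gain <- if (cells$group[i] == "high") trialGain else rep(1, nT)
      drive <- driveBase <- numeric(nFrames)
      if (any(fire)) {
        sel <- tid %in% which(fire)
        d <- .circDistCm(pos[sel], centreCm, tl)
        env <- exp(-d^2 / (2 * sigmaCm^2))
        driveBase[sel] <- env
        drive[sel] <- env * gain[tid[sel]]
      }
      base <- convDecay(driveBase)
      signal <- convDecay(drive)
      ## normalize so the ungained event peak equals the drawn amplitude
      ## regardless of field width and crossing speed
      if (any(base > 0)) {
        scale <- amp / max(base)
        signal <- signal * scale
        base <- base * scale
      }
      ## event extent at half maximum of the (gain-modulated) event height
      mask[i, ] <- signal > 0.5 * amp * gain[tid]
    } else {
      drive <- numeric(nFrames)
      nEv <- rpois(1, untunedRateHz * nFrames / fr)
      if (nEv > 0) drive[sample.int(nFrames, nEv)] <- amp
      signal <- convDecay(drive)
      ## impulse response peaks at amp * max(kernel); restore the peak
      if (any(signal > 0)) signal <- signal / max(kernel)
      mask[i, ] <- signal > 0.5 * amp
    }
    mat[i, ] <- signal + rnorm(nFrames, 0, config@noiseSd)
  }
  rownames(mat) <- paste0("cell", seq_len(n))
  session <- .withTraces(session, mat)
  truth@eventMask <- mask
  truth@sessions <- data.frame(
    cell_id = rep(seq_len(n), nT),
    trial = rep(seq_len(nT), each = n),
    event = as.vector(trialEvent))
  list(session = session, truth = truth)
}

#' Simulate per-cell fold-induction values
#'
#' fold = baseline + gain x standardized integrated dF/F + Gaussian noise,
#' truncated below at a small positive floor, so induction increases with a
#' cell's integrated activity when `inductionGain > 0`.
#'
#' @param truth a [GroundTruth-class] (for the intended group labels).
#' @param session a session with a dff assay.
#' @param config a [SimConfig-class].
#' @param seed RNG seed.
#' @param floor lower truncation of the fold values.
#' @return data.frame: cell_id, fold_induction, intended_group.
#' @export
simulateInduction <- function(truth, session, config, seed = config@seed,
                              floor = 0.05) {
  set.seed(.substreamSeed(seed, "induction"))
  act <- rowSums(dff(session)) / frameRate(session)
  z <- if (sd(act) > 0) (act - mean(act)) / sd(act) else rep(0, length(act))
  fold <- config@inductionBaseline + config@inductionGain * z +
    rnorm(length(act), 0, config@inductionNoiseSd)
  data.frame(cell_id = truth@cells$cell_id,
             fold_induction = pmax(fold, floor),
             intended_group = truth@cells$group)
}

#' Simulate one complete session
#'
#' Behaviour, ground truth, traces and induction from one master seed via
#' named substreams, so each artefact is independently reproducible.
#'
#' @param config a [SimConfig-class].
#' @param seed master RNG seed.
#' @param truth optional pre-built [GroundTruth-class] (used by the
#'   multi-session generator to share cells across days).
#' @return list(session, truth, induction).
#' @export
simulateSession <- function(config, seed = config@seed, truth = NULL) {
  if (is.null(truth)) truth <- simulateGroundTruth(config, seed)
  beh <- simulateBehavior(config, seed)
  tr <- simulateTraces(beh, truth, config, seed)
  ind <- simulateInduction(tr$truth, tr$session, config, seed)
  list(session = tr$session, truth = tr$truth, induction = ind)
}

#' Simulate an aligned multi-day session set
#'
#' Cells are shared across sessions. Between consecutive sessions each tuned
#' cell keeps its field with its per-cell persistence probability
#' `stability_rho`; otherwise it relocates the field (probability
#' `remapFraction`) or loses it. A fraction `missingFraction` of cells is
#' absent from each session after the first, emulating imperfect cross-day
#' matching; the alignment table maps global cell ids to per-session ids.
#'
#' @param config a [SimConfig-class] with `nSessions >= 2`.
#' @param seed master RNG seed.
#' @return list with `sessions` (list of per-session lists as returned by
#'   [simulateSession()]), `alignment` (data.frame global_id, session,
#'   local_id), and `truths` (per-session ground truth).
#' @export
simulateMultiSession <- function(config, seed = config@seed) {
  if (config@nSessions < 2) stop("nSessions must be >= 2")
  baseTruth <- simulateGroundTruth(config, seed)
  n <- config@nCells
  cells <- baseTruth@cells
  sessions <- vector("list", config@nSessions)
  truths <- vector("list", config@nSessions)
  alignRows <- list()
  set.seed(.substreamSeed(seed, "multiday"))
  persist <- matrix(TRUE, n, config@nSessions)
  for (s in seq_len(config@nSessions)) {
    if (s > 1) {
      keep <- runif(n) < cells$stability_rho
      relocate <- !keep & runif(n) < config@remapFraction
      lose <- !keep & !relocate
      cells$field_center_bin[relocate & cells$is_tuned] <-
        sample.int(config@nBins, sum(relocate & cells$is_tuned),
                   replace = TRUE) - 1L
      drop <- lose & cells$is_tuned
      cells$is_tuned[drop] <- FALSE
      cells$field_center_bin[drop] <- NA_integer_
      cells$field_width_bins[drop] <- NA
      cells$field_width_cm[drop] <- NA
      persist[, s] <- keep
    }
    present <- if (s == 1) rep(TRUE, n) else runif(n) >= config@missingFraction
    sTruth <- baseTruth
    sTruth@cells <- cells[present, , drop = FALSE]
    sessSeed <- .substreamSeed(seed, paste0("session", s))
    bundle <- simulateSession(config, seed = sessSeed, truth = sTruth)
    sessions[[s]] <- bundle
    truths[[s]] <- bundle$truth
    alignRows[[s]] <- data.frame(global_id = cells$cell_id[present],
                                 session = s,
                                 local_id = seq_len(sum(present)))
  }
  list(sessions = sessions, alignment = do.call(rbind, alignRows),
       truths = truths, persistence = persist)
}
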