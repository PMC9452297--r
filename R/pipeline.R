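## Session-bundle I/O and the end-to-end pipeline: signals -> behaviour ->
## tuning -> decoding -> induction -> ensembles -> stability on one or more
## session bundles.

#' Write a session bundle to a directory
#'
#' Plain-text layout: `traces.csv` (cells x frames dF/F), `behavior.csv`
#' (frame, position, speed, trialId), `trials.csv`, `licks.csv`,
#' `rewards.csv`, `induction.csv`, and a `config.yaml` echo of the session
#' geometry.
#'
#' @param session a [CalciumSession-class].
#' @param dir output directory (created).
#' @param induction optional per-cell induction table.
#' @return `dir`, invisibly.
#' @export
writeSessionBundle <- function(session, dir, induction = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(dff(session)),
                     file.path(dir, "traces.csv"), col.names = FALSE)
  beh <- data.frame(frame = seq_len(ncol(session)),
                    position = position(session), speed = speed(session),
                    trialId = trialId(session))
  data.table::fwrite(beh, file.path(dir, "behavior.csv"))
  data.table::fwrite(trials(session), file.path(dir, "trials.csv"))
  data.table::fwrite(licks(session), file.path(dir, "licks.csv"))
  data.table::fwrite(rewards(session), file.path(dir, "rewards.csv"))
  if (!is.null(induction))
    data.table::fwrite(induction, file.path(dir, "induction.csv"))
  yaml::write_yaml(list(frame_rate_hz = frameRate(session),
                        track_length_cm = trackLength(session),
                        reward_zone_cm = as.numeric(rewardZone(session))),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a session bundle written by [writeSessionBundle()]
#'
#' @param dir bundle directory.
#' @return list(session (annotated [CalciumSession-class]), induction
#'   (data.frame or NULL)).
#' @export
readSessionBundle <- function(dir) {
  need <- c("traces.csv", "behavior.csv", "trials.csv", "licks.csv",
            "rewards.csv", "config.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("bundle ", dir, " is missing: ", paste(missing, collapse = ", "))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  beh <- data.table::fread(file.path(dir, "behavior.csv"), data.table = FALSE)
  traces <- as.matrix(data.table::fread(file.path(dir, "traces.csv"),
                                        header = FALSE, data.table = FALSE))
  dimnames(traces) <- NULL
  if (ncol(traces) != nrow(beh))
    stop("traces.csv and behavior.csv disagree on the frame count")
  lk <- data.table::fread(file.path(dir, "licks.csv"), data.table = FALSE)
  rw <- data.table::fread(file.path(dir, "rewards.csv"), data.table = FALSE)
  tt <- data.table::fread(file.path(dir, "trials.csv"), data.table = FALSE)
  x <- CalciumSession(position = beh$position, speed = beh$speed,
                      trialId = beh$trialId, frameRate = cfg$frame_rate_hz,
                      trackLength = cfg$track_length_cm,
                      rewardZone = cfg$reward_zone_cm, dff = traces,
                      licks = lk, rewards = rw, trials = tt)
  x <- annotateTrials(x, trialTypes = tt$type)
  ind <- if (file.exists(file.path(dir, "induction.csv")))
    data.table::fread(file.path(dir, "induction.csv"), data.table = FALSE)
  else NULL
  list(session = x, induction = ind)
}

#' Simulate session bundles on disk
#'
#' Generates one session (or an aligned multi-day set when
#' `config@nSessions >= 2`) and writes each as a bundle directory
#' (`session1`, `session2`, ...) plus an `alignment.csv` for multi-day sets.
#'
#' @param config a [SimConfig-class].
#' @param outDir output directory.
#' @param seed master seed.
#' @return `outDir`, invisibly.
#' @export
simulateBundle <- function(config, outDir, seed = config@seed) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (config@nSessions >= 2) {
    ms <- simulateMultiSession(config, seed)
    for (s in seq_along(ms$sessions))
      writeSessionBundle(ms$sessions[[s]]$session,
                         file.path(outDir, paste0("session", s)),
                         ms$sessions[[s]]$induction)
    data.table::fwrite(ms$alignment, file.path(outDir, "alignment.csv"))
  } else {
    b <- simulateSession(config, seed)
    writeSessionBundle(b$session, file.path(outDir, "session1"),
                       b$induction)
  }
  invisible(outDir)
}

#' @noRd
.groupIdx <- function(groupTab, label) {
  which(!is.na(groupTab$group) & groupTab$group == label)
}

#' Run the full analysis pipeline on simulated or loaded bundles
#'
#' Executes transient detection, behaviour summaries, spatial tuning with the
#' shuffle null, per-decile decoding, induction grouping, activity matching,
#' trial-wise ensemble analysis and (for multi-day inputs with an alignment
#' table) cross-day within-group correlations and activity-weighted
#' stability maps.
#'
#' @param bundles either the return value of [simulateMultiSession()], a list
#'   with elements `sessions` (list of `list(session, induction)`) and
#'   optional `alignment`, or a single `list(session, induction)`.
#' @param nShuffles shuffles for the place-field null.
#' @param seed master seed.
#' @param minStabilityCells minimum group size for a stability map.
#' @param outDir optional directory for CSV outputs.
#' @return list with `perSession` (per-session summary data.frame), `cells`
#'   (per-cell table across sessions), `stability` (per session-pair, per
#'   group), `crossday` (within-group correlation by session gap), `params`.
#' @export
runPipeline <- function(bundles, nShuffles = 200, seed = 1,
                        minStabilityCells = 20, outDir = NULL) {
  if (!is.null(bundles[["session"]]))
    bundles <- list(sessions = list(bundles))
  sessions <- bundles[["sessions"]]
  alignment <- bundles[["alignment"]]
  nS <- length(sessions)

  perSession <- list()
  cellRows <- list()
  tunings <- vector("list", nS)
  groupTabs <- vector("list", nS)
  activations <- vector("list", nS)
  sesList <- vector("list", nS)

  for (s in seq_len(nS)) {
    ses <- detectTransients(sessions[[s]]$session)
    sesList[[s]] <- ses
    ind <- sessions[[s]]$induction
    elig <- eligibleTrials(ses)
    tun <- computeSpatialTuning(ses, nShuffles = nShuffles,
                                seed = .substreamSeed(seed,
                                                      paste0("tuning", s)))
    tunings[[s]] <- tun
    alpha <- integratedDff(ses)

    groupTab <- NULL
    decLow <- decHigh <- NA_real_
    corrHigh <- corrLow <- NA_real_
    ratioHigh <- ratioLow <- NA_real_
    matchGap <- NA_real_
    if (is.null(ind))
      message("session ", s, ": no induction table; induction-dependent ",
              "stages (decoding by decile, ensembles, matching) skipped")
    if (!is.null(ind)) {
      groupTab <- assignInductionGroups(ind$fold_induction,
                                        cellIds = ind$cell_id)
      groupTabs[[s]] <- groupTab
      dec <- decodeByDecile(ses, groupTab$decile)
      decLow <- dec$low; decHigh <- dec$high
      hi <- .groupIdx(groupTab, "high"); lo <- .groupIdx(groupTab, "low")
      pc <- which(isPlaceCell(tun))
      if (sum(hi %in% pc) >= 2 && sum(lo %in% pc) >= 2) {
        am <- activationMatrix(tun)
        activations[[s]] <- am
        wg <- withinGroupCorrelation(am, list(high = intersect(hi, pc),
                                              low = intersect(lo, pc)))
        corrHigh <- wg[["high"]]; corrLow <- wg[["low"]]
        cl <- clusterCells(am)
        sc <- sameClusterVsChance(cl$labels,
                                  list(high = match(intersect(hi, pc), pc),
                                       low = match(intersect(lo, pc), pc)),
                                  nPerm = 200,
                                  seed = .substreamSeed(seed,
                                                        paste0("perm", s)))
        ratioHigh <- sc$ratio[sc$group == "high"]
        ratioLow <- sc$ratio[sc$group == "low"]
      }
      if (length(hi) && length(lo) && any(alpha[hi] > 0) &&
          any(alpha[lo] > 0)) {
        m <- activityMatch(alpha, hi, lo,
                           seed = .substreamSeed(seed, paste0("match", s)))
        if (length(m$high))
          matchGap <- abs(mean(alpha[m$high]) - mean(alpha[m$low]))
      }
    }

    fracPlace <- function(idx) if (length(idx)) mean(isPlaceCell(tun)[idx])
      else NA_real_
    hiIdx <- if (!is.null(groupTab)) .groupIdx(groupTab, "high") else integer(0)
    loIdx <- if (!is.null(groupTab)) .groupIdx(groupTab, "low") else integer(0)
    perSession[[s]] <- data.frame(
      session = s,
      selectivity = lickingSelectivity(ses),
      n_eligible_trials = length(elig),
      n_place_cells = sum(isPlaceCell(tun)),
      frac_place_high = fracPlace(hiIdx), frac_place_low = fracPlace(loIdx),
      hnorm_high = if (length(hiIdx)) mean(tun@Hnorm[hiIdx], na.rm = TRUE)
        else NA_real_,
      hnorm_low = if (length(loIdx)) mean(tun@Hnorm[loIdx], na.rm = TRUE)
        else NA_real_,
      decoder_error_low_cm = decLow, decoder_error_high_cm = decHigh,
      within_corr_high = corrHigh, within_corr_low = corrLow,
      cluster_ratio_high = ratioHigh, cluster_ratio_low = ratioLow,
      matched_alpha_gap = matchGap)

    cellRows[[s]] <- data.frame(
      session = s, cell = seq_len(nrow(ses)), alpha = alpha,
      H = tun@H, H_norm = tun@Hnorm, place_cell = isPlaceCell(tun),
      decile = if (!is.null(groupTab)) groupTab$decile else NA_integer_,
      group = if (!is.null(groupTab)) groupTab$group else NA_character_)
  }

  ## cross-day analyses over every positive-gap session pair
  stabRows <- list()
  crossRows <- list()
  if (nS >= 2 && !is.null(alignment)) {
    toGlobal <- function(s) {
      al <- alignment[alignment$session == s, ]
      al$global_id[order(al$local_id)]
    }
    for (ref in seq_len(nS - 1)) for (tgt in (ref + 1):nS) {
      gRef <- toGlobal(ref); gTgt <- toGlobal(tgt)
      shared <- intersect(gRef, gTgt)
      if (!length(shared)) next
      refLoc <- match(shared, gRef); tgtLoc <- match(shared, gTgt)
      gt <- groupTabs[[ref]]
      if (is.null(gt)) next
      for (lab in c("high", "low")) {
        gIdx <- .groupIdx(gt, lab)
        sel <- which(refLoc %in% gIdx &
                     isPlaceCell(tunings[[ref]])[refLoc])
        if (length(sel) < minStabilityCells) next
        refT <- tuningCurves(tunings[[ref]])[refLoc[sel], , drop = FALSE]
        tgtT <- tuningCurves(tunings[[tgt]])[tgtLoc[sel], , drop = FALSE]
        x <- placefieldCorrelation(refT, tgtT)
        if (sum(!is.na(x)) < minStabilityCells) next
        sm <- stabilityMap(x, refT, group = lab, dSessions = tgt - ref,
                           minCells = minStabilityCells)
        zs <- zoneSummary(sm, rewardZone(sesList[[ref]]),
                          trackLength(sesList[[ref]]))
        stabRows[[length(stabRows) + 1L]] <- data.frame(
          ref = ref, target = tgt, d_sessions = tgt - ref, group = lab,
          n_cells = sm@nCells,
          mean_stability = mean(sm@stability, na.rm = TRUE),
          peri_reward = zs[["peri_reward"]], no_reward = zs[["no_reward"]])
      }
      ## cross-day within-group activation correlation
      if (!is.null(activations[[tgt]])) {
        amT <- activations[[tgt]]
        pcT <- which(isPlaceCell(tunings[[tgt]]))
        colnames(amT) <- as.character(gTgt[pcT])
        grps <- lapply(c(high = "high", low = "low"), function(lab)
          gRef[.groupIdx(gt, lab)])
        ok <- vapply(grps, function(g)
          sum(as.character(g) %in% colnames(amT)) >= 2, logical(1))
        if (all(ok)) {
          cc <- crossdayWithinGroup(amT, grps)
          crossRows[[length(crossRows) + 1L]] <- data.frame(
            ref = ref, target = tgt, d_sessions = tgt - ref,
            corr_high = cc[["high"]], corr_low = cc[["low"]])
        }
      }
    }
  }

  out <- list(perSession = do.call(rbind, perSession),
              cells = do.call(rbind, cellRows),
              stability = if (length(stabRows)) do.call(rbind, stabRows)
                else NULL,
              crossday = if (length(crossRows)) do.call(rbind, crossRows)
                else NULL,
              params = list(nShuffles = nShuffles, seed = seed,
                            minStabilityCells = minStabilityCells))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(out$perSession, file.path(outDir, "sessions.csv"))
    data.table::fwrite(out$cells, file.path(outDir, "cells.csv"))
    if (!is.null(out$stability))
      data.table::fwrite(out$stability, file.path(outDir, "stability.csv"))
    if (!is.null(out$crossday))
      data.table::fwrite(out$crossday, file.path(outDir, "crossday.csv"))
    yaml::write_yaml(out$params, file.path(outDir, "params.yaml"))
  }
  out
}
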