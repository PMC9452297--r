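#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment colData assay assayNames
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors metadata DataFrame SimpleList
#' @importFrom stats median quantile sd cor rnorm runif rpois rbinom rlnorm
#'   mad setNames dnorm
#' @importFrom utils head tail combn
NULL

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Configuration of the synthetic virtual-track experiment
#'
#' Holds the geometry of the task (a circular 200-cm track with a hidden 20-cm
#' reward zone), the trial structure (standard / crutch / probe trial types),
#' the statistical structure of the simulated place code (per-cell field
#' centre, width, amplitude and trial-to-trial reliability), the calcium
#' forward model (single-exponential event kernel plus additive noise), the
#' Fos fold-induction model (induction increases with integrated activity),
#' and the multi-day persistence model. Use [simConfig()] to build one.
#'
#' @slot trackLengthCm track length in cm.
#' @slot nBins number of spatial bins (bin width = trackLengthCm / nBins).
#' @slot frameRateHz imaging / behaviour frame rate in Hz.
#' @slot rewardZone numeric(2), start and end of the reward zone in cm.
#' @slot nTrials number of trials (laps) per session.
#' @slot trialTypeFractions named numeric(3), fractions of standard, crutch and
#'   probe trials.
#' @slot nCells number of simulated cells.
#' @slot pTuned probability a cell carries a ground-truth place field.
#' @slot fieldWidthCm numeric(2), uniform range of field widths (Gaussian
#'   envelope s.d. in cm is width / 4).
#' @slot amplitude numeric(2), uniform range of event amplitudes (dF/F units).
#' @slot reliability numeric(2), uniform range of per-cell trial reliability
#'   (probability the field emits an event on a lap).
#' @slot eventDecayS calcium event exponential decay constant in seconds.
#' @slot noiseSd s.d. of additive Gaussian trace noise (dF/F units).
#' @slot inductionBaseline,inductionGain,inductionNoiseSd fold-induction model:
#'   fold = baseline + gain * standardized integrated dF/F + noise.
#' @slot speedMeanCmS,speedSdLog lognormal per-trial running speed model.
#' @slot rewardZoneSlowFactor multiplicative speed factor inside the reward zone.
#' @slot lickPolicy "expert" (licks concentrated just before and inside the
#'   reward zone) or "novice" (uniform along the track).
#' @slot licksPerTrial mean number of test licks per trial.
#' @slot rewardVolumeMl volume of one reward.
#' @slot nSessions number of sessions for multi-day simulation.
#' @slot tuningStabilityRho numeric(2): day-to-day field persistence
#'   probability range; each cell's rho interpolates over this range with its
#'   reliability, coupling induction to stability.
#' @slot remapFraction probability a non-persisting field relocates rather
#'   than disappears.
#' @slot missingFraction fraction of cells absent from any given session
#'   (imperfect cross-day matching).
#' @slot ensembleGainSd s.d. (log scale) of a per-trial shared gain applied to
#'   the event amplitudes of the high-reliability ("high") cell tier, planting
#'   ensemble-like co-fluctuation of in-field activity across trials; 0
#'   disables it.
#' @slot seed default RNG seed.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  trackLengthCm = "numeric", nBins = "integer", frameRateHz = "numeric",
  rewardZone = "numeric", nTrials = "integer", trialTypeFractions = "numeric",
  nCells = "integer", pTuned = "numeric", fieldWidthCm = "numeric",
  amplitude = "numeric", reliability = "numeric", eventDecayS = "numeric",
  noiseSd = "numeric", inductionBaseline = "numeric", inductionGain = "numeric",
  inductionNoiseSd = "numeric", speedMeanCmS = "numeric", speedSdLog = "numeric",
  rewardZoneSlowFactor = "numeric", lickPolicy = "character",
  licksPerTrial = "numeric", rewardVolumeMl = "numeric", nSessions = "integer",
  tuningStabilityRho = "numeric", remapFraction = "numeric",
  missingFraction = "numeric", ensembleGainSd = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@trackLengthCm <= 0) msg <- c(msg, "trackLengthCm must be positive")
  if (object@nBins < 1) msg <- c(msg, "nBins must be >= 1")
  if (object@frameRateHz <= 0) msg <- c(msg, "frameRateHz must be positive")
  rz <- object@rewardZone
  if (length(rz) != 2 || rz[1] < 0 || rz[2] > object@trackLengthCm || rz[1] >= rz[2])
    msg <- c(msg, "rewardZone must be [start, end) inside [0, trackLengthCm)")
  if (object@nTrials < 1) msg <- c(msg, "at least one trial is required")
  f <- object@trialTypeFractions
  if (length(f) != 3 || any(f < 0) || abs(sum(f) - 1) > 1e-8)
    msg <- c(msg, "trialTypeFractions must be 3 nonnegative values summing to 1")
  probs <- c(object@pTuned, object@reliability, object@tuningStabilityRho,
             object@remapFraction, object@missingFraction)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "all probabilities must be in [0, 1]")
  if (object@eventDecayS <= 0) msg <- c(msg, "eventDecayS must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (object@ensembleGainSd < 0)
    msg <- c(msg, "ensembleGainSd must be nonnegative")
  if (!object@lickPolicy %in% c("expert", "novice"))
    msg <- c(msg, "lickPolicy must be 'expert' or 'novice'")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated session set
#'
#' @slot cells per-cell truth: tuned flag, field centre bin, field width in
#'   bins, reliability, amplitude, stability rho and intended induction group
#'   ("high" / "mid" / "low", tiered by reliability).
#' @slot eventMask logical cells x frames matrix marking frames belonging to a
#'   ground-truth calcium event (filled by [simulateTraces()]).
#' @slot sessions per-session, per-cell field outcome for multi-day sets.
#' @slot config the [SimConfig-class] used.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  cells = "data.frame", eventMask = "matrix", sessions = "data.frame",
  config = "SimConfig"
))

setValidity("GroundTruth", function(object) {
  cells <- object@cells
  need <- c("cell_id", "is_tuned", "field_center_bin", "field_width_bins",
            "reliability_p", "amplitude", "group")
  if (!all(need %in% names(cells))) return("cells is missing required columns")
  if (any(cells$is_tuned & is.na(cells$field_center_bin)))
    return("every tuned cell must have a field centre")
  if (any(!cells$is_tuned & !is.na(cells$field_center_bin)))
    return("untuned cells must have no field")
  TRUE
})

## ---------------------------------------------------------------------------
## Session container
## ---------------------------------------------------------------------------

#' Frame-synchronized imaging session
#'
#' Extends [SummarizedExperiment::SummarizedExperiment-class]: rows are cells,
#' columns are imaging frames. Assays hold cells x frames traces (`"dff"` for
#' raw dF/F; `"transients"` is added by [detectTransients()] and holds the
#' significance-masked zero-baseline trace). Per-frame behaviour (position on
#' the circular track, running speed, trial id) lives in `colData`; event
#' tables (licks, rewards, trials) and session geometry live in `metadata`.
#'
#' @exportClass CalciumSession
setClass("CalciumSession", contains = "SummarizedExperiment")

setValidity("CalciumSession", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("position", "speed", "trialId")
  if (!all(need %in% names(cd)))
    return("colData must contain position, speed and trialId")
  md <- S4Vectors::metadata(object)
  for (f in c("frameRate", "trackLength", "rewardZone"))
    if (is.null(md[[f]])) return(paste0("metadata$", f, " is required"))
  pos <- cd$position
  if (any(pos < 0 | pos >= md$trackLength))
    return("position must lie in [0, trackLength)")
  if (any(cd$speed < 0)) return("speed must be nonnegative")
  if (is.unsorted(cd$trialId)) return("trialId must be nondecreasing")
  TRUE
})

#' Construct a CalciumSession
#'
#' @param position per-frame position in cm on the circular track.
#' @param speed per-frame speed in cm/s.
#' @param trialId per-frame trial index (1-based, nondecreasing).
#' @param frameRate frames per second.
#' @param trackLength track length in cm.
#' @param rewardZone numeric(2) reward zone (start, end) in cm.
#' @param dff optional cells x frames dF/F matrix.
#' @param licks data.frame with columns `frame`, `kind` ("test"/"consumption"),
#'   `trial`, `position`.
#' @param rewards data.frame with columns `frame`, `volume`, `manual`, `trial`.
#' @param trials data.frame of per-trial records (see [annotateTrials()]).
#' @return a [CalciumSession-class].
#' @export
CalciumSession <- function(position, speed, trialId, frameRate, trackLength,
                           rewardZone, dff = NULL,
                           licks = .emptyLicks(), rewards = .emptyRewards(),
                           trials = NULL) {
  n <- length(position)
  assays <- if (is.null(dff)) {
    S4Vectors::SimpleList()
  } else {
    stopifnot(ncol(dff) == n)
    S4Vectors::SimpleList(dff = dff)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(position = position, speed = speed,
                                   trialId = as.integer(trialId)),
    metadata = list(frameRate = frameRate, trackLength = trackLength,
                    rewardZone = rewardZone, licks = licks, rewards = rewards,
                    trials = trials)
  )
  if (is.null(dff)) {
    ## zero-row assay keeps ncol defined by colData
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = S4Vectors::SimpleList(dff = matrix(numeric(0), 0, n)),
      colData = SummarizedExperiment::colData(se),
      metadata = S4Vectors::metadata(se))
  }
  new("CalciumSession", se)
}

#' Replace the trace matrix of a session, keeping behaviour and metadata
#' @noRd
.withTraces <- function(session, mat) {
  stopifnot(ncol(mat) == ncol(session))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(dff = mat),
    colData = SummarizedExperiment::colData(session),
    metadata = S4Vectors::metadata(session))
  new("CalciumSession", se)
}

.emptyLicks <- function() {
  data.frame(frame = integer(0), kind = character(0), trial = integer(0),
             position = numeric(0))
}

.emptyRewards <- function() {
  data.frame(frame = integer(0), volume = numeric(0), manual = logical(0),
             trial = integer(0))
}

## ---------------------------------------------------------------------------
## Transients
## ---------------------------------------------------------------------------

#' Significance-masked dF/F trace of one cell
#'
#' The output of [detectSignificantTransients()]: the original dF/F values on
#' frames belonging to a significant transient, exactly zero elsewhere, plus
#' per-transient records and summary statistics (including the integrated
#' dF/F, `alpha`).
#'
#' @slot dff masked zero-baseline dF/F trace.
#' @slot mask per-frame significance flags.
#' @slot events one row per retained transient: start/end frame (1-based,
#'   inclusive), duration in frames, peak dF/F, integral in dF/F x s, and the
#'   accepting threshold/length pair recorded for post-hoc auditing.
#' @slot stats list: transients_per_second, mean_duration_s, mean_peak,
#'   mean_integral, alpha (sum of significant dF/F x frame duration), empty.
#' @slot frameRate frames per second.
#' @exportClass TransientTrace
setClass("TransientTrace", representation(
  dff = "numeric", mask = "logical", events = "data.frame", stats = "list",
  frameRate = "numeric"
))

setValidity("TransientTrace", function(object) {
  if (length(object@dff) != length(object@mask))
    return("dff and mask lengths differ")
  if (any(object@dff[!object@mask] != 0))
    return("non-significant frames must be exactly zero")
  if (nrow(object@events) && any(object@events$duration_frames < 2))
    return("every retained transient must span >= 2 frames")
  a <- object@stats$alpha
  if (!is.null(a) && a < 0) return("alpha must be nonnegative")
  TRUE
})

## ---------------------------------------------------------------------------
## Spatial tuning
## ---------------------------------------------------------------------------

#' Spatial tuning of a cell population in one session
#'
#' Binned and circularly smoothed tuning curves, the 99th-percentile
#' block-permutation shuffle null, detected place fields, and spatial
#' information for each cell.
#'
#' @slot occupancy fraction of contributing (running, eligible-trial) frames
#'   per spatial bin; sums to 1.
#' @slot perTrial trials x bins x cells array of per-trial mean binned
#'   activity (NA where a bin was not visited on that trial).
#' @slot meanActivity cells x bins session-mean binned activity.
#' @slot smoothed cells x bins circularly smoothed tuning curves.
#' @slot nullCurve cells x bins elementwise 99th percentile of the shuffles.
#' @slot H,Hnorm spatial information per cell (bits) and its shuffle-mean
#'   normalization.
#' @slot shuffleHMean per-cell mean of spatial information over shuffles.
#' @slot fields one row per place field: cell, start_bin (0-based), n_bins,
#'   peak_bin, width_cm. Fields are maximal circular runs of >= 3 significant
#'   bins.
#' @slot placeCell per-cell flag: has at least one field.
#' @slot eligibleTrials the trial ids used.
#' @slot params list of analysis parameters (run threshold, kernel sigma,
#'   number of shuffles, seed).
#' @exportClass SpatialTuningSet
setClass("SpatialTuningSet", representation(
  occupancy = "numeric", perTrial = "array", meanActivity = "matrix",
  smoothed = "matrix", nullCurve = "matrix", H = "numeric", Hnorm = "numeric",
  shuffleHMean = "numeric", fields = "data.frame", placeCell = "logical",
  eligibleTrials = "integer", params = "list"
))

setValidity("SpatialTuningSet", function(object) {
  occ <- object@occupancy
  if (sum(occ) > 0 && abs(sum(occ) - 1) > 1e-8) return("occupancy must sum to 1")
  if (any(object@H < -1e-12, na.rm = TRUE)) return("spatial information must be >= 0")
  if (nrow(object@fields) && any(object@fields$n_bins < 3))
    return("every field must span >= 3 bins")
  TRUE
})

## ---------------------------------------------------------------------------
## Decoding
## ---------------------------------------------------------------------------

#' Poisson naive-Bayes decoder templates
#'
#' @slot templates cells x bins mean binned activity from training (even)
#'   trials, floored at `epsilon`.
#' @slot tau temporal bin in seconds (one frame).
#' @slot epsilon template floor applied before logs.
#' @slot trainTrials trial ids used for training.
#' @slot validBins bins visited during training; others are excluded from the
#'   posterior support.
#' @exportClass TemplateSet
setClass("TemplateSet", representation(
  templates = "matrix", tau = "numeric", epsilon = "numeric",
  trainTrials = "integer", validBins = "logical"
))

#' Result of decoding a session
#'
#' @slot decodedBin,trueBin 0-based spatial bin per test frame.
#' @slot errorCm circular decoding error per frame (0..trackLength/2).
#' @slot frames indices of the decoded frames in the session.
#' @slot meanError mean error in cm.
#' @slot errorByBin mean error per true bin.
#' @slot posterior frames x bins posterior (rows sum to 1); empty unless
#'   requested.
#' @exportClass DecodingResult
setClass("DecodingResult", representation(
  decodedBin = "integer", trueBin = "integer", errorCm = "numeric",
  frames = "integer", meanError = "numeric", errorByBin = "numeric",
  posterior = "matrix"
))

setValidity("DecodingResult", function(object) {
  if (length(object@errorCm) && any(object@errorCm < 0))
    return("errors must be nonnegative")
  TRUE
})

## ---------------------------------------------------------------------------
## Stability
## ---------------------------------------------------------------------------

#' Activity-weighted cross-day stability map
#'
#' Per-track-bin weighted mean of per-cell reference-to-target tuning
#' correlations `x`; the weight of a cell at a bin is its sum-normalized
#' reference tuning there, so each place field contributes equally and only
#' where the cell was active.
#'
#' @slot stability per-bin weighted mean of x (NA at zero-weight bins).
#' @slot x per-cell Pearson correlation between reference and target tuning.
#' @slot weights cells x bins sum-normalized reference tuning.
#' @slot cellIds the contributing cells.
#' @slot group group label ("high", "low", "KO", "WT", ...).
#' @slot dSessions target minus reference session index.
#' @slot nCells number of contributing cells (>= 20 by construction).
#' @exportClass StabilityMap
setClass("StabilityMap", representation(
  stability = "numeric", x = "numeric", weights = "matrix",
  cellIds = "integer", group = "character", dSessions = "integer",
  nCells = "integer"
))

setValidity("StabilityMap", function(object) {
  w <- object@weights
  if (nrow(w) != length(object@x)) return("weights rows must match x")
  rs <- rowSums(w)
  if (any(abs(rs[rs > 0] - 1) > 1e-8))
    return("per-cell weights must sum to 1")
  TRUE
})
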