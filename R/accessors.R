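## Accessor generics and show methods.

#' @rdname CalciumSession
#' @param object,x a `CalciumSession`.
#' @export
setGeneric("position", function(x) standardGeneric("position"))
#' @rdname CalciumSession
#' @export
setMethod("position", "CalciumSession", function(x)
  SummarizedExperiment::colData(x)$position)

#' @rdname CalciumSession
#' @export
setGeneric("speed", function(x) standardGeneric("speed"))
#' @rdname CalciumSession
#' @export
setMethod("speed", "CalciumSession", function(x)
  SummarizedExperiment::colData(x)$speed)

#' @rdname CalciumSession
#' @export
setGeneric("trialId", function(x) standardGeneric("trialId"))
#' @rdname CalciumSession
#' @export
setMethod("trialId", "CalciumSession", function(x)
  SummarizedExperiment::colData(x)$trialId)

#' @rdname CalciumSession
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname CalciumSession
#' @export
setMethod("frameRate", "CalciumSession", function(x)
  S4Vectors::metadata(x)$frameRate)

#' @rdname CalciumSession
#' @export
setGeneric("trackLength", function(x) standardGeneric("trackLength"))
#' @rdname CalciumSession
#' @export
setMethod("trackLength", "CalciumSession", function(x)
  S4Vectors::metadata(x)$trackLength)

#' @rdname CalciumSession
#' @export
setGeneric("rewardZone", function(x) standardGeneric("rewardZone"))
#' @rdname CalciumSession
#' @export
setMethod("rewardZone", "CalciumSession", function(x)
  S4Vectors::metadata(x)$rewardZone)

#' @rdname CalciumSession
#' @export
setGeneric("licks", function(x) standardGeneric("licks"))
#' @rdname CalciumSession
#' @export
setMethod("licks", "CalciumSession", function(x) S4Vectors::metadata(x)$licks)

#' @rdname CalciumSession
#' @export
setGeneric("rewards", function(x) standardGeneric("rewards"))
#' @rdname CalciumSession
#' @export
setMethod("rewards", "CalciumSession", function(x)
  S4Vectors::metadata(x)$rewards)

#' @rdname CalciumSession
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname CalciumSession
#' @export
setMethod("trials", "CalciumSession", function(x) S4Vectors::metadata(x)$trials)

#' @rdname CalciumSession
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))
#' @rdname CalciumSession
#' @export
setMethod("dff", "CalciumSession", function(x)
  SummarizedExperiment::assay(x, "dff"))

#' @rdname CalciumSession
#' @export
setGeneric("transientTraces", function(x) standardGeneric("transientTraces"))
#' @rdname CalciumSession
#' @export
setMethod("transientTraces", "CalciumSession", function(x) {
  if (!"transients" %in% SummarizedExperiment::assayNames(x))
    stop("run detectTransients() first")
  SummarizedExperiment::assay(x, "transients")
})

#' @rdname CalciumSession
#' @export
setGeneric("transientStats", function(x) standardGeneric("transientStats"))
#' @rdname CalciumSession
#' @export
setMethod("transientStats", "CalciumSession", function(x) {
  s <- S4Vectors::metadata(x)$transientStats
  if (is.null(s)) stop("run detectTransients() first")
  s
})

setMethod("show", "CalciumSession", function(object) {
  md <- S4Vectors::metadata(object)
  cat("CalciumSession:", nrow(object), "cells x", ncol(object), "frames @",
      md$frameRate, "Hz\n")
  cat("  track", md$trackLength, "cm; reward zone [", md$rewardZone[1], ",",
      md$rewardZone[2], ") cm\n")
  tr <- md$trials
  if (!is.null(tr))
    cat("  ", nrow(tr), " trials (", sum(tr$eligible), " eligible); ",
        nrow(md$licks), " licks; ", nrow(md$rewards), " rewards\n", sep = "")
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
})

#' @rdname TransientTrace
#' @param x a `TransientTrace`.
#' @export
setGeneric("transientEvents", function(x) standardGeneric("transientEvents"))
#' @rdname TransientTrace
#' @export
setMethod("transientEvents", "TransientTrace", function(x) x@events)

#' Integrated dF/F (alpha) of a trace or session
#'
#' Sum of the significance-masked dF/F over frames, times the frame duration;
#' the per-cell activity measure used for activity matching.
#' @param x a `TransientTrace` or `CalciumSession` with detected transients.
#' @return numeric scalar (trace) or per-cell vector (session).
#' @export
setGeneric("integratedDff", function(x) standardGeneric("integratedDff"))
#' @rdname integratedDff
#' @export
setMethod("integratedDff", "TransientTrace", function(x) x@stats$alpha)
#' @rdname integratedDff
#' @export
setMethod("integratedDff", "CalciumSession", function(x)
  transientStats(x)$alpha)

setMethod("show", "TransientTrace", function(object) {
  cat("TransientTrace:", length(object@dff), "frames,",
      nrow(object@events), "significant transients\n")
  cat("  rate", signif(object@stats$transients_per_second, 3), "/s; alpha",
      signif(object@stats$alpha, 4), "\n")
})

#' @rdname SpatialTuningSet
#' @param x a `SpatialTuningSet`.
#' @export
setGeneric("isPlaceCell", function(x) standardGeneric("isPlaceCell"))
#' @rdname SpatialTuningSet
#' @export
setMethod("isPlaceCell", "SpatialTuningSet", function(x) x@placeCell)

#' @rdname SpatialTuningSet
#' @export
setGeneric("placeFields", function(x) standardGeneric("placeFields"))
#' @rdname SpatialTuningSet
#' @export
setMethod("placeFields", "SpatialTuningSet", function(x) x@fields)

#' @rdname SpatialTuningSet
#' @export
setGeneric("spatialInfo", function(x) standardGeneric("spatialInfo"))
#' @rdname SpatialTuningSet
#' @export
setMethod("spatialInfo", "SpatialTuningSet", function(x)
  data.frame(cell = seq_along(x@H), H = x@H, H_norm = x@Hnorm))

#' @rdname SpatialTuningSet
#' @export
setGeneric("tuningCurves", function(x) standardGeneric("tuningCurves"))
#' @rdname SpatialTuningSet
#' @export
setMethod("tuningCurves", "SpatialTuningSet", function(x) x@smoothed)

#' @rdname SpatialTuningSet
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))
#' @rdname SpatialTuningSet
#' @export
setMethod("occupancy", "SpatialTuningSet", function(x) x@occupancy)

setMethod("show", "SpatialTuningSet", function(object) {
  cat("SpatialTuningSet:", nrow(object@meanActivity), "cells x",
      ncol(object@meanActivity), "bins;",
      sum(object@placeCell), "place cells,", nrow(object@fields), "fields\n")
  cat("  ", length(object@eligibleTrials), " eligible trials; ",
      object@params$nShuffles, " shuffles\n", sep = "")
})

setMethod("show", "TemplateSet", function(object) {
  cat("TemplateSet:", nrow(object@templates), "cells x",
      ncol(object@templates), "bins; tau", signif(object@tau, 4),
      "s; epsilon", signif(object@epsilon, 4), "\n")
})

#' @rdname DecodingResult
#' @param x a `DecodingResult`.
#' @export
setGeneric("decodingError", function(x) standardGeneric("decodingError"))
#' @rdname DecodingResult
#' @export
setMethod("decodingError", "DecodingResult", function(x) x@errorCm)

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult:", length(object@errorCm), "frames; mean error",
      signif(object@meanError, 4), "cm\n")
})

#' @rdname StabilityMap
#' @param x a `StabilityMap`.
#' @export
setGeneric("stabilityValues", function(x) standardGeneric("stabilityValues"))
#' @rdname StabilityMap
#' @export
setMethod("stabilityValues", "StabilityMap", function(x) x@stability)

setMethod("show", "StabilityMap", function(object) {
  cat("StabilityMap (", object@group, ", d=", object@dSessions, "): ",
      object@nCells, " cells; mean stability ",
      signif(mean(object@stability, na.rm = TRUE), 3), "\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@trackLengthCm, "cm track /", object@nBins,
      "bins @", object@frameRateHz, "Hz;", object@nTrials, "trials;",
      object@nCells, "cells;", object@nSessions, "session(s)\n")
})
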