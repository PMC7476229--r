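#' Accessors for pipeline containers
#'
#' Small accessor generics so that downstream code never touches slots
#' directly: `sampleRate()`, `channelLabels()`, `eventTable()`,
#' `subjectID()`, `visitIndex()`, `trialStatus()`, `artifactFlags()`,
#' `rejectedElectrodes()`, `erpWaveform()`, `includedTrialCounts()`,
#' `componentInclusion()`, `transitionCounts()` and
#' `transitionProbabilities()`.
#'
#' @param object a pipeline container.
#' @param ... passed to methods.
#' @return the corresponding slot value (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("visitIndex", function(object) standardGeneric("visitIndex"))

#' @rdname accessors
#' @export
setGeneric("trialStatus", function(object) standardGeneric("trialStatus"))

#' @rdname accessors
#' @export
setGeneric("artifactFlags", function(object) standardGeneric("artifactFlags"))

#' @rdname accessors
#' @export
setGeneric("rejectedElectrodes", function(object) standardGeneric("rejectedElectrodes"))

#' @rdname accessors
#' @param condition `"face"` or `"house"`.
#' @export
setGeneric("erpWaveform", function(object, condition) standardGeneric("erpWaveform"))

#' @rdname accessors
#' @export
setGeneric("includedTrialCounts", function(object) standardGeneric("includedTrialCounts"))

#' @rdname accessors
#' @export
setGeneric("componentInclusion", function(object) standardGeneric("componentInclusion"))

#' @rdname accessors
#' @export
setGeneric("transitionCounts", function(object) standardGeneric("transitionCounts"))

#' @rdname accessors
#' @export
setGeneric("transitionProbabilities", function(object) standardGeneric("transitionProbabilities"))

#' @rdname accessors
setMethod("sampleRate", "RawRecording", function(object) object@sampleRate)
#' @rdname accessors
setMethod("channelLabels", "RawRecording", function(object) object@channels)
#' @rdname accessors
setMethod("eventTable", "RawRecording", function(object) object@events)
#' @rdname accessors
setMethod("subjectID", "RawRecording", function(object) object@subject)
#' @rdname accessors
setMethod("visitIndex", "RawRecording", function(object) object@visit)

#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(object) object@channels)
#' @rdname accessors
setMethod("subjectID", "EpochSet", function(object) object@subject)
#' @rdname accessors
setMethod("visitIndex", "EpochSet", function(object) object@visit)
#' @rdname accessors
setMethod("trialStatus", "EpochSet", function(object) object@trialStatus)
#' @rdname accessors
setMethod("artifactFlags", "EpochSet", function(object) object@flags)
#' @rdname accessors
setMethod("rejectedElectrodes", "EpochSet", function(object) object@rejectedChannels)

#' @rdname accessors
setMethod("channelLabels", "SubjectERP", function(object) object@channels)
#' @rdname accessors
setMethod("subjectID", "SubjectERP", function(object) object@subject)
#' @rdname accessors
setMethod("visitIndex", "SubjectERP", function(object) object@visit)
#' @rdname accessors
setMethod("erpWaveform", "SubjectERP", function(object, condition) {
  condition <- match.arg(condition, c("face", "house"))
  object@waveforms[[condition]]
})
#' @rdname accessors
setMethod("includedTrialCounts", "SubjectERP", function(object) object@nTrials)
#' @rdname accessors
setMethod("componentInclusion", "SubjectERP", function(object) object@inclusion)

#' @rdname accessors
setMethod("transitionCounts", "TransitionTable", function(object) object@counts)
#' @rdname accessors
setMethod("transitionProbabilities", "TransitionTable", function(object) object@probabilities)

#' @describeIn accessors epoch time axis (ms) of an `EpochSet`.
#' @export
epochTimes <- function(object) object@times

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nSubjects, "subjects x 2 visits,",
      2L * object@nTrialsPerCondition, "trials in", object@nBlocks, "blocks\n")
  cat(sprintf("  %d channels @ %g Hz; ISI %g-%g ms; trial %g ms\n",
              length(object@channels), object@sampleRate,
              object@isiRange[1], object@isiRange[2], object@trialDuration))
  cat(sprintf("  noise %g uV (pink fraction %g); artifact rate %g; look-away rate %g; seed %d\n",
              object@noiseSd, object@pinkNoiseFraction, object@artifactRate,
              object@lookawayRate, object@seed))
})

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording %s visit %d: %d channels x %d samples @ %g Hz, %d events\n",
              object@subject, object@visit, nrow(object@data), ncol(object@data),
              object@sampleRate, nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  st <- table(object@trialStatus)
  cat(sprintf("EpochSet %s visit %d: %d trials x %d channels x %d samples (%.1f to %.1f ms)\n",
              object@subject, object@visit, dim(object@data)[3],
              dim(object@data)[1], dim(object@data)[2],
              min(object@times), max(object@times)))
  cat("  trial status:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  nrej <- sum(object@rejectedChannels != "")
  if (nrej) cat("  rejected electrodes:", nrej, "\n")
  if (object@referenced) cat("  common-average referenced\n")
})

setMethod("show", "SubjectERP", function(object) {
  cat(sprintf("SubjectERP %s visit %d: %d channels, %d samples per condition\n",
              object@subject, object@visit, length(object@channels),
              length(object@times)))
  inc <- object@inclusion
  cat("  included families:",
      if (any(inc)) paste(names(inc)[inc], collapse = ", ") else "none", "\n")
})

setMethod("show", "TransitionTable", function(object) {
  cat(sprintf("TransitionTable %s (threshold %g uV, n = %d)\n",
              object@component, object@threshold, object@n))
  print(object@counts)
  s <- object@summary
  if (length(s))
    cat(sprintf("  dominant %s: share V1 %s%%, V2 %s%%; persistence %s%%; movers-in %s%%; both visits %s%%\n",
                paste(s$dominant, collapse = "/"), s$dominantShareV1,
                s$dominantShareV2, s$persistence, s$moverShare,
                s$bothVisitShare))
})
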