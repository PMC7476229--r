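#' @import methods
NULL

## Central data containers of the pipeline.  All voltages are in microvolt
## (uV), all times in milliseconds unless a slot name says otherwise.

#' Cohort simulation configuration
#'
#' Parameters of the synthetic longitudinal cohort generator: task structure
#' (trial counts, durations, inter-stimulus interval), recording parameters
#' (sample rate, montage), noise model and contamination rates.
#'
#' @slot nSubjects number of infants in the cohort.
#' @slot nTrialsPerCondition face (and house) trials per visit.
#' @slot nBlocks number of presentation blocks; each block shows every
#'   stimulus identity once in randomized order.
#' @slot trialDuration stimulus duration in ms.
#' @slot isiRange jittered inter-stimulus interval range in ms, low/high.
#' @slot sampleRate acquisition rate in Hz; must be an integer multiple of
#'   512 so that decimation to the 512 Hz analysis rate is exact.
#' @slot channels montage labels (10-20 system).
#' @slot noiseSd total background-noise standard deviation per channel, uV.
#' @slot pinkNoiseFraction fraction of noise variance carried by 1/f
#'   ("pink") noise; the remainder is white.
#' @slot artifactRate probability that a trial x electrode receives an
#'   injected artifact (spike, flatline or step, chosen uniformly).
#' @slot lookawayRate probability that a trial is flagged as the infant
#'   looking away from the screen.
#' @slot seed integer seed from which all randomness derives.
#'
#' @seealso [cohortConfig()] for the user-facing constructor with defaults.
#' @export
setClass("CohortConfig", representation(
  nSubjects = "integer",
  nTrialsPerCondition = "integer",
  nBlocks = "integer",
  trialDuration = "numeric",
  isiRange = "numeric",
  sampleRate = "numeric",
  channels = "character",
  noiseSd = "numeric",
  pinkNoiseFraction = "numeric",
  artifactRate = "numeric",
  lookawayRate = "numeric",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if ((2L * object@nTrialsPerCondition) %% object@nBlocks != 0L)
    msg <- c(msg, "total trial count must be divisible by nBlocks")
  if (length(object@isiRange) != 2L || object@isiRange[1] > object@isiRange[2])
    msg <- c(msg, "isiRange must be c(low, high) with low <= high")
  rates <- c(object@pinkNoiseFraction, object@artifactRate, object@lookawayRate)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "pinkNoiseFraction, artifactRate and lookawayRate must lie in [0, 1]")
  if (object@sampleRate %% 512 != 0)
    msg <- c(msg, "sampleRate must be an integer multiple of 512 Hz")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be at least 1")
  if (anyDuplicated(object@channels)) msg <- c(msg, "channel labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Raw continuous EEG recording for one subject-visit
#'
#' A channels x samples voltage trace with stimulus event markers.  The
#' event table carries one row per presented trial: onset sample (1-based),
#' condition (`"face"`/`"house"`), block index, and a look-away flag.
#'
#' @slot subject subject identifier.
#' @slot visit visit index (1 or 2).
#' @slot sampleRate sampling rate in Hz.
#' @slot channels channel labels, one per data row.
#' @slot data channels x samples matrix, uV.
#' @slot events data.frame with columns `onset`, `condition`, `block`,
#'   `lookaway`.
#' @export
setClass("RawRecording", representation(
  subject = "character",
  visit = "integer",
  sampleRate = "numeric",
  channels = "character",
  data = "matrix",
  events = "data.frame"
))

setValidity("RawRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "data must have one row per channel")
  need <- c("onset", "condition", "block", "lookaway")
  if (!all(need %in% names(object@events)))
    msg <- c(msg, sprintf("events must have columns %s", paste(need, collapse = ", ")))
  else {
    if (nrow(object@events) &&
        (min(object@events$onset) < 1 ||
         max(object@events$onset) > ncol(object@data)))
      msg <- c(msg, "all event onsets must fall within the trace")
    if (!all(object@events$condition %in% c("face", "house")))
      msg <- c(msg, "conditions must be 'face' or 'house'")
  }
  if (!(object@visit %in% c(1L, 2L))) msg <- c(msg, "visit must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Epoched, baseline-corrected trials for one subject-visit
#'
#' Trials cut from -200 to 1000 ms around stimulus onset at the analysis
#' rate, with per-trial-per-electrode artifact flags (reason codes
#' `"amplitude"`, `"flatline"`, `"gradient"` or `""`), per-trial status
#' (`"included"`, `"excluded:lookaway"`, `"excluded:artifact-fraction"`,
#' `"excluded:reference"`), and per-electrode rejection flags.
#'
#' @slot subject,visit identifiers.
#' @slot times epoch time axis in ms relative to stimulus onset.
#' @slot channels electrode labels.
#' @slot data array channel x time x trial, uV.
#' @slot condition,block,lookaway per-trial descriptors.
#' @slot flags character matrix channel x trial of artifact reason codes.
#' @slot trialStatus per-trial inclusion status.
#' @slot rejectedChannels per-channel rejection reason (`""` if retained).
#' @slot referenced whether the common-average reference has been applied.
#' @slot log named list of per-stage bookkeeping counts.
#' @export
setClass("EpochSet", representation(
  subject = "character",
  visit = "integer",
  times = "numeric",
  channels = "character",
  data = "array",
  condition = "character",
  block = "integer",
  lookaway = "logical",
  flags = "matrix",
  trialStatus = "character",
  rejectedChannels = "character",
  referenced = "logical",
  log = "list"
))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L)
    return("data must be a channel x time x trial array")
  if (d[1] != length(object@channels)) msg <- c(msg, "channel dimension mismatch")
  if (d[2] != length(object@times)) msg <- c(msg, "time dimension mismatch")
  if (d[3] != length(object@condition)) msg <- c(msg, "trial dimension mismatch")
  if (length(object@trialStatus) != d[3]) msg <- c(msg, "trialStatus length mismatch")
  if (!all(dim(object@flags) == c(d[1], d[3]))) msg <- c(msg, "flags must be channel x trial")
  if (length(object@rejectedChannels) != d[1])
    msg <- c(msg, "rejectedChannels length mismatch")
  if (length(msg)) msg else TRUE
})

#' Per-condition average ERP for one subject-visit
#'
#' The event-related potential per condition per electrode, together with
#' the number of artifact-free trials that contributed per electrode and
#' the inclusion flags per component family (a family is included only when
#' every critical electrode has at least the required trials in both
#' conditions).
#'
#' @slot subject,visit identifiers.
#' @slot times epoch time axis in ms.
#' @slot channels electrode labels.
#' @slot waveforms named list (`face`, `house`) of channel x time matrices;
#'   rejected electrodes are `NA`.
#' @slot nTrials channel x condition matrix of contributing trial counts.
#' @slot inclusion named logical vector per component family
#'   (`P1`, `N290P400`, `Nc`).
#' @slot usable `FALSE` when the whole subject-visit is unusable (e.g. all
#'   electrodes rejected).
#' @export
setClass("SubjectERP", representation(
  subject = "character",
  visit = "integer",
  times = "numeric",
  channels = "character",
  waveforms = "list",
  nTrials = "matrix",
  inclusion = "logical",
  usable = "logical"
))

setValidity("SubjectERP", function(object) {
  msg <- character()
  if (!all(c("face", "house") %in% names(object@waveforms)))
    msg <- c(msg, "waveforms must contain 'face' and 'house'")
  for (w in object@waveforms)
    if (!all(dim(w) == c(length(object@channels), length(object@times))))
      msg <- c(msg, "waveform dimension mismatch")
  if (length(msg)) unique(msg) else TRUE
})

#' Between-visit state-transition table for one component
#'
#' A 3 x 3 contingency of face-house difference states (negative / none /
#' positive) at Visit 1 (rows) against Visit 2 (columns), with
#' row-normalized transition probabilities and the descriptive summary
#' percentages used to compare components (dominant-group share per visit,
#' persistence, mover-to-dominant share, both-visit dominant share).
#'
#' @slot component component name.
#' @slot threshold state-classification threshold in uV.
#' @slot counts 3 x 3 integer matrix of subjects.
#' @slot probabilities row-normalized transition probabilities; rows with
#'   zero marginal are `NaN`.
#' @slot n number of classified subjects.
#' @slot summary list produced by [summarizeDominant()].
#' @seealso [buildTransitionTable()], [summarizeDominant()]
#' @export
setClass("TransitionTable", representation(
  component = "character",
  threshold = "numeric",
  counts = "matrix",
  probabilities = "matrix",
  n = "integer",
  summary = "list"
))

setValidity("TransitionTable", function(object) {
  msg <- character()
  if (!all(dim(object@counts) == c(3L, 3L)))
    msg <- c(msg, "counts must be 3 x 3")
  if (sum(object@counts) != object@n)
    msg <- c(msg, "counts must sum to the number of classified subjects")
  rs <- rowSums(object@counts)
  p <- object@probabilities
  ok <- rs > 0
  if (any(ok) && any(abs(rowSums(p[ok, , drop = FALSE]) - 1) > 1e-12))
    msg <- c(msg, "probability rows with non-zero marginal must sum to 1")
  if (any(!ok) && !all(is.nan(p[!ok, ])))
    msg <- c(msg, "probability rows with zero marginal must be NaN")
  if (length(msg)) msg else TRUE
})
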