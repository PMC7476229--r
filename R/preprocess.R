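## Epoching, baseline correction, artifact flagging, electrode/trial
## rejection, common-average referencing and per-condition averaging.

#' Cut epochs and apply baseline correction
#'
#' Extracts one epoch per stimulus event, from 200 ms before to 1000 ms
#' after onset, and subtracts the mean of the -150 to 0 ms baseline window
#' per electrode per trial.  Events whose epoch would exceed the trace
#' bounds are skipped and counted in the log.
#'
#' @param raw a [RawRecording-class] at the analysis rate.
#' @param baselineWindow baseline interval in ms (closed).
#' @return an [EpochSet-class] with all trials initially `"included"`.
#' @export
segmentEpochs <- function(raw, baselineWindow = c(-150, 0)) {
  fs <- raw@sampleRate
  rel <- -round(0.2 * fs):round(1.0 * fs)
  times <- rel / fs * 1000
  ev <- raw@events
  ok <- ev$onset + rel[1] >= 1 & ev$onset + rel[length(rel)] <= ncol(raw@data)
  if (any(!ok))
    message(sum(!ok), " event(s) skipped: epoch exceeds trace bounds")
  ev <- ev[ok, , drop = FALSE]
  nCh <- length(raw@channels)
  dat <- array(NA_real_, c(nCh, length(rel), nrow(ev)),
               dimnames = list(raw@channels, NULL, NULL))
  for (tr in seq_len(nrow(ev)))
    dat[, , tr] <- raw@data[, ev$onset[tr] + rel, drop = FALSE]
  bIdx <- windowIndex(times, baselineWindow)
  base <- apply(dat[, bIdx, , drop = FALSE], c(1, 3), mean)
  for (tr in seq_len(dim(dat)[3]))
    dat[, , tr] <- dat[, , tr] - base[, tr]
  new("EpochSet", subject = raw@subject, visit = raw@visit, times = times,
      channels = raw@channels, data = dat, condition = ev$condition,
      block = as.integer(ev$block), lookaway = ev$lookaway,
      flags = matrix("", nCh, nrow(ev)),
      trialStatus = rep("included", nrow(ev)),
      rejectedChannels = rep("", nCh), referenced = FALSE,
      log = list(presented = nrow(raw@events), skipped = sum(!ok)))
}

#' Flag artifacts per trial and electrode
#'
#' Look-away trials are excluded whole.  For the remaining trials each
#' electrode is scanned between 0 and 600 ms post-stimulus and flagged
#' when any of three criteria fires (strict inequalities; first match wins
#' as the reason code):
#'
#' 1. `amplitude`: any sample exceeding +/-200 uV;
#' 2. `flatline`: any 200 ms sliding window whose peak-to-peak range is
#'    below 3 uV;
#' 3. `gradient`: any consecutive-sample change above 50 uV.
#'
#' @param epochs a baseline-corrected [EpochSet-class].
#' @param ampThreshold absolute amplitude bound, uV.
#' @param flatRange minimum peak-to-peak range, uV.
#' @param flatWindow sliding-window length, ms.
#' @param gradThreshold per-sample change bound, uV.
#' @param scanWindow post-stimulus scan region, ms (closed).
#' @return the [EpochSet-class] with `flags` and look-away exclusions set.
#' @export
flagArtifacts <- function(epochs, ampThreshold = 200, flatRange = 3,
                          flatWindow = 200, gradThreshold = 50,
                          scanWindow = c(0, 600)) {
  fs <- 1000 / diff(epochs@times[1:2])
  idx <- windowIndex(epochs@times, scanWindow)
  w <- round(flatWindow / 1000 * fs) + 1L
  epochs@trialStatus[epochs@lookaway] <- "excluded:lookaway"
  nCh <- length(epochs@channels)
  for (tr in which(!epochs@lookaway)) {
    seg <- matrix(epochs@data[, idx, tr], nrow = nCh)
    amp <- apply(abs(seg) > ampThreshold, 1, any)
    flat <- slidingMinRangeCpp(t(seg), w) < flatRange
    grad <- apply(abs(seg[, -1, drop = FALSE] -
                        seg[, -ncol(seg), drop = FALSE]) > gradThreshold,
                  1, any)
    reason <- ifelse(amp, "amplitude",
              ifelse(flat, "flatline",
              ifelse(grad, "gradient", "")))
    epochs@flags[, tr] <- reason
  }
  epochs@log$lookaway <- sum(epochs@lookaway)
  epochs
}

#' Apply trial and electrode rejection
#'
#' Two rules, in this order: (1) a trial is removed whole when its flagged
#' electrodes exceed 16 percent of the montage (strict; with 32 channels,
#' 6 or more flagged electrodes remove the trial); (2) an electrode is
#' rejected when it has fewer than 5 artifact-free trials among the
#' surviving included trials, pooled over conditions.  Trial removal runs
#' first so that a globally bad trial cannot doom electrodes.
#'
#' @param epochs a flagged [EpochSet-class].
#' @param maxBadFraction trial-removal threshold as a fraction of the full
#'   montage (strict inequality).
#' @param minFreeTrials minimum artifact-free trials per electrode.
#' @return the [EpochSet-class] with trial statuses and electrode
#'   rejections set; when every electrode is rejected the subject-visit is
#'   recorded as unusable in the log.
#' @export
applyRejection <- function(epochs, maxBadFraction = 0.16,
                           minFreeTrials = 5) {
  nCh <- length(epochs@channels)
  inc <- epochs@trialStatus == "included"
  nFlag <- colSums(epochs@flags != "")
  kill <- inc & nFlag > maxBadFraction * nCh
  epochs@trialStatus[kill] <- "excluded:artifact-fraction"
  inc <- epochs@trialStatus == "included"
  free <- rowSums(epochs@flags[, inc, drop = FALSE] == "")
  epochs@rejectedChannels <- ifelse(free < minFreeTrials,
                                    "insufficient-free-trials", "")
  epochs@log$artifactFraction <- sum(kill)
  epochs@log$rejectedElectrodes <- sum(epochs@rejectedChannels != "")
  epochs@log$unusable <- all(epochs@rejectedChannels != "")
  epochs
}

#' Apply the common-average reference
#'
#' For every included trial, the per-sample mean over that trial's usable
#' electrodes (unflagged and not rejected) is subtracted from each usable
#' electrode.  Flagged or rejected electrodes neither contribute to nor
#' receive the reference.  Trials with fewer than two usable electrodes
#' are excluded with a log entry.
#'
#' @param epochs an [EpochSet-class] after rejection.
#' @return the referenced [EpochSet-class].
#' @export
applyAverageReference <- function(epochs) {
  keepCh <- epochs@rejectedChannels == ""
  nRef <- 0L
  for (tr in which(epochs@trialStatus == "included")) {
    usable <- keepCh & epochs@flags[, tr] == ""
    if (sum(usable) < 2L) {
      epochs@trialStatus[tr] <- "excluded:reference"
      nRef <- nRef + 1L
      next
    }
    ref <- colMeans(epochs@data[usable, , tr, drop = FALSE])
    epochs@data[usable, , tr] <- sweep(
      epochs@data[usable, , tr, drop = FALSE], 2, ref)[, , 1]
  }
  epochs@log$reference <- nRef
  epochs@referenced <- TRUE
  epochs
}

#' Average epochs into a per-condition subject ERP
#'
#' Per condition per electrode, the arithmetic mean over included trials
#' in which that electrode is unflagged.  A subject-visit is included for
#' a component family only when every critical electrode of that family is
#' retained and has at least `minTrials` contributing trials in both
#' conditions.
#'
#' @param epochs a referenced [EpochSet-class].
#' @param minTrials inclusion threshold per critical electrode per
#'   condition.
#' @return a [SubjectERP-class].
#' @export
averageByCondition <- function(epochs, minTrials = 10) {
  nCh <- length(epochs@channels)
  nT <- length(epochs@times)
  keepCh <- epochs@rejectedChannels == ""
  waveforms <- list()
  nTrials <- matrix(0L, nCh, 2, dimnames = list(epochs@channels,
                                                c("face", "house")))
  for (cond in c("face", "house")) {
    wf <- matrix(NA_real_, nCh, nT, dimnames = list(epochs@channels, NULL))
    trs <- which(epochs@trialStatus == "included" &
                   epochs@condition == cond)
    for (ch in which(keepCh)) {
      use <- trs[epochs@flags[ch, trs] == ""]
      nTrials[ch, cond] <- length(use)
      if (length(use)) {
        slice <- matrix(epochs@data[ch, , use], nrow = nT)
        wf[ch, ] <- rowMeans(slice)
      }
    }
    waveforms[[cond]] <- wf
  }
  crit <- criticalElectrodes()
  inclusion <- vapply(crit, function(el) {
    rows <- match(el, epochs@channels)
    !anyNA(rows) && all(keepCh[rows]) && all(nTrials[rows, ] >= minTrials)
  }, logical(1))
  new("SubjectERP", subject = epochs@subject, visit = epochs@visit,
      times = epochs@times, channels = epochs@channels,
      waveforms = waveforms, nTrials = nTrials, inclusion = inclusion,
      usable = any(keepCh))
}

#' Run the full preprocessing chain for one recording
#'
#' Filter and downsample, epoch and baseline-correct, exclude look-away
#' trials, flag artifacts, reject trials/electrodes, re-reference to the
#' common average, and average per condition.  `flagging = FALSE` skips
#' the artifact criteria and rejection rules (look-away exclusion still
#' applies), which is useful for clean validation runs on noise-free data
#' where the flatline criterion would correctly fire everywhere.
#'
#' @param raw a [RawRecording-class] at any multiple of 512 Hz.
#' @param flagging apply artifact criteria and rejection rules.
#' @param referencing apply the common-average reference.
#' @param minTrials inclusion threshold, see [averageByCondition()].
#' @param ... passed on to [flagArtifacts()] and [applyRejection()].
#' @return a [SubjectERP-class].
#' @export
preprocessRecording <- function(raw, flagging = TRUE, referencing = TRUE,
                                minTrials = 10, ...) {
  args <- list(...)
  raw <- filterAndDownsample(raw)
  epochs <- segmentEpochs(raw)
  if (flagging) {
    fa <- args[intersect(names(args), names(formals(flagArtifacts)))]
    epochs <- do.call(flagArtifacts, c(list(epochs), fa))
    ar <- args[intersect(names(args), names(formals(applyRejection)))]
    epochs <- do.call(applyRejection, c(list(epochs), ar))
  } else {
    epochs@trialStatus[epochs@lookaway] <- "excluded:lookaway"
  }
  if (referencing) epochs <- applyAverageReference(epochs)
  averageByCondition(epochs, minTrials = minTrials)
}
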