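## End-to-end orchestration: simulate (or read) raw recordings, preprocess,
## score, classify trajectories, and run the inferential statistics, with
## per-stage bookkeeping and TSV persistence.

#' Pipeline configuration
#'
#' Bundles all stage parameters.  Defaults reproduce the analysis settings
#' of the emulated study: 0.1-30 Hz zero-phase band-pass with 50 Hz notch,
#' 512 Hz analysis rate, -200 to 1000 ms epochs with -150 to 0 ms
#' baseline, the three artifact criteria (200 uV / 3 uV in 200 ms / 50 uV
#' per sample) scanned 0-600 ms, the 16 percent trial rule and 5-trial
#' electrode rule, common-average reference, 10-trial inclusion rule, and
#' the 1.5 uV state threshold.
#'
#' @param cohort a [CohortConfig-class] for the simulate stage.
#' @param effects effect specification, see [defaultEffectSpec()].
#' @param groupMeans group-level targets, see [defaultGroupMeans()].
#' @param threshold state-classification threshold, uV.
#' @param minTrials inclusion rule: minimum contributing trials per
#'   critical electrode per condition.
#' @param flagging,referencing stage toggles for artifact flagging /
#'   rejection and common-average referencing.
#' @param simulate generate the cohort (`TRUE`) or read recordings from
#'   `inputDir`.
#' @param inputDir directory of recordings written by [writeRecording()]
#'   (used when `simulate = FALSE`; subjects/visits are discovered from
#'   file names).
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(cohort = cohortConfig(),
                           effects = defaultEffectSpec(),
                           groupMeans = defaultGroupMeans(),
                           threshold = 1.5,
                           minTrials = 10,
                           flagging = TRUE,
                           referencing = TRUE,
                           simulate = TRUE,
                           inputDir = NULL) {
  structure(list(cohort = cohort, effects = effects,
                 groupMeans = groupMeans, threshold = threshold,
                 minTrials = minTrials, flagging = flagging,
                 referencing = referencing, simulate = simulate,
                 inputDir = inputDir),
            class = "pipelineConfig")
}

preprocessWithLog <- function(raw, config) {
  raw <- filterAndDownsample(raw)
  epochs <- segmentEpochs(raw)
  if (config$flagging) {
    epochs <- flagArtifacts(epochs)
    epochs <- applyRejection(epochs)
  } else {
    epochs@trialStatus[epochs@lookaway] <- "excluded:lookaway"
    epochs@log$lookaway <- sum(epochs@lookaway)
  }
  if (config$referencing) epochs <- applyAverageReference(epochs)
  erp <- averageByCondition(epochs, minTrials = config$minTrials)
  lg <- epochs@log
  lg$included <- sum(epochs@trialStatus == "included")
  list(erp = erp, log = lg)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) every subject-visit recording, preprocesses it,
#' scores the ERP components, computes face-house difference scores and
#' per-component transition tables, and runs the inferential layer:
#' per-component 2x2 ANOVAs on mean amplitude and on peak-to-trough
#' amplitude, the P1 latency ANOVA, the N290 face-latency paired t-test,
#' and Brown-Forsythe tests of between-visit variance homogeneity of the
#' difference scores.  Deterministic given the cohort seed.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory; when given, all tables are
#'   written as TSV (`scores.tsv`, `differences.tsv`, `transitions.tsv`,
#'   `anova.tsv`, `ttests.tsv`, `brown_forsythe.tsv`, `runlog.tsv`, and
#'   the ground-truth tables for simulated cohorts).
#' @param verbose print progress.
#' @return list of class `pipelineResult`: `erps`, `scores`,
#'   `differences`, `transitions`, `anovas`, `ttests`, `brownForsythe`,
#'   `log`, and `groundTruth` (simulated runs).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        verbose = FALSE) {
  cohort <- NULL
  if (config$simulate) {
    cohort <- generateCohort(config$cohort, config$effects,
                             config$groupMeans)
    subjects <- cohort$subjects
    getRec <- cohort$recording
  } else {
    if (is.null(config$inputDir)) stop("inputDir required when simulate = FALSE")
    files <- list.files(config$inputDir, pattern = "_v[12]_eeg\\.tsv$")
    subjects <- unique(sub("_v[12]_eeg\\.tsv$", "", files))
    if (!length(subjects)) stop("no recordings found in ", config$inputDir)
    getRec <- function(s, v) readRecording(config$inputDir, s, v)
  }

  erps <- list()
  logRows <- list()
  for (s in subjects) for (v in 1:2) {
    if (verbose) message("preprocessing ", s, " visit ", v)
    res <- preprocessWithLog(getRec(s, v), config)
    erps[[paste(s, v)]] <- res$erp
    lg <- res$log
    logRows[[paste(s, v)]] <- data.frame(
      subject = s, visit = v,
      presented = lg$presented, skipped = lg$skipped %||% 0L,
      lookaway = lg$lookaway %||% 0L,
      artifact_fraction = lg$artifactFraction %||% 0L,
      reference = lg$reference %||% 0L,
      included = lg$included,
      rejected_electrodes = lg$rejectedElectrodes %||% 0L,
      stringsAsFactors = FALSE)
  }
  runLog <- do.call(rbind, logRows)
  rownames(runLog) <- NULL

  scores <- scoreComponents(erps)
  diffs <- differenceScores(scores)
  tabs <- transitionTables(diffs, threshold = config$threshold)

  ## inferential layer
  anovaRows <- list()
  addAnova <- function(component, measure, fit) {
    ## analyses that cannot be computed (e.g. too few complete cases) are
    ## reported as absent rather than aborting the run
    if (inherits(fit, "try-error") || is.null(fit)) return(invisible())
    anovaRows[[length(anovaRows) + 1L]] <<- data.frame(
      component = component, measure = measure, effect = fit$effect,
      F = fit$F, df1 = fit$df1, df2 = fit$df2, p = fit$p,
      petaSq = fit$petaSq, n = attr(fit, "n"), stringsAsFactors = FALSE)
  }
  safeFit <- function(tbl) tryCatch(rmAnova2x2(tbl), error = function(e) NULL)
  longFor <- function(measure, component) {
    s <- scores[scores$measure == measure & scores$component == component, ]
    data.frame(subject = s$subject, stimulus = s$condition,
               visit = s$visit, value = s$value)
  }
  for (comp in scoredComponents())
    addAnova(comp, "mean_amplitude", safeFit(longFor("mean_amplitude", comp)))
  for (comp in c("P1", "N290", "P400"))
    addAnova(comp, "peak_to_trough", safeFit(longFor("peak_to_trough", comp)))
  addAnova("P1", "peak_latency", safeFit(longFor("peak_latency", "P1")))
  anovas <- do.call(rbind, anovaRows)

  ## N290 face-latency development: paired t across visits
  lat <- scores[scores$measure == "peak_latency" &
                  scores$component == "N290" & scores$condition == "face", ]
  l1 <- lat[lat$visit == 1, ]
  l2 <- lat[lat$visit == 2, ]
  m <- match(l1$subject, l2$subject)
  ok <- !is.na(l1$value) & !is.na(l2$value[m])
  ttests <- NULL
  if (sum(ok) >= 2) {
    tt <- pairedTTest(l1$value[ok], l2$value[m][ok])
    ttests <- data.frame(component = "N290",
                         measure = "peak_latency_face_v1_minus_v2",
                         t = tt$t, df = tt$df, p = tt$p, d = tt$d,
                         mean_diff = tt$meanDiff, n = tt$n,
                         stringsAsFactors = FALSE)
  }

  ## variance homogeneity of difference scores between visits
  bfRows <- list()
  for (comp in scoredComponents()) {
    d <- diffs[diffs$component == comp & !is.na(diffs$value), ]
    if (all(table(d$visit) >= 2) && length(unique(d$visit)) == 2) {
      bf <- brownForsythe(d$value, d$visit)
      bfRows[[comp]] <- data.frame(component = comp, F = bf$F,
                                   df1 = bf$df1, df2 = bf$df2, p = bf$p,
                                   stringsAsFactors = FALSE)
    }
  }
  bfTab <- do.call(rbind, bfRows)
  rownames(bfTab) <- NULL

  result <- structure(list(
    erps = erps, scores = scores, differences = diffs, transitions = tabs,
    anovas = anovas, ttests = ttests, brownForsythe = bfTab, log = runLog,
    groundTruth = if (!is.null(cohort)) cohort$groundTruth),
    class = "pipelineResult")

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeScores(scores, file.path(outDir, "scores.tsv"))
    writeTsv(diffs, file.path(outDir, "differences.tsv"))
    writeTransitionTables(tabs, file.path(outDir, "transitions.tsv"))
    writeTsv(anovas, file.path(outDir, "anova.tsv"))
    if (!is.null(ttests)) writeTsv(ttests, file.path(outDir, "ttests.tsv"))
    if (!is.null(bfTab)) writeTsv(bfTab, file.path(outDir, "brown_forsythe.tsv"))
    writeTsv(runLog, file.path(outDir, "runlog.tsv"))
    if (!is.null(cohort)) {
      writeTsv(cohort$groundTruth$means,
               file.path(outDir, "ground_truth_means.tsv"))
      writeTsv(cohort$groundTruth$differences,
               file.path(outDir, "ground_truth_differences.tsv"))
    }
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipelineResult <- function(x, ...) {
  cat(sprintf("pipelineResult: %d subject-visits, %d score rows, %d transition tables\n",
              length(x$erps), nrow(x$scores), length(x$transitions)))
  invisible(x)
}

#' Grand-average waveforms in long format
#'
#' Averages the per-subject condition waveforms across subjects, per
#' visit, exporting a tidy table (electrode, time_ms, condition, visit,
#' amplitude) suitable for plotting.
#'
#' @param erps list of [SubjectERP-class] objects.
#' @return long-format data.frame.
#' @export
grandAverage <- function(erps) {
  rows <- list()
  for (v in 1:2) for (cond in c("face", "house")) {
    sel <- Filter(function(e) e@visit == v, erps)
    if (!length(sel)) next
    mats <- lapply(sel, function(e) e@waveforms[[cond]])
    avg <- Reduce(`+`, lapply(mats, function(m) ifelse(is.na(m), 0, m))) /
      Reduce(`+`, lapply(mats, function(m) 0 + !is.na(m)))
    times <- sel[[1]]@times
    rows[[paste(v, cond)]] <- data.frame(
      electrode = rep(rownames(avg), ncol(avg)),
      time_ms = rep(times, each = nrow(avg)),
      condition = cond, visit = v, amplitude = as.vector(avg),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
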