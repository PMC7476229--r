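## Synthetic raw-EEG rendering: trial plans, 1/f + white noise, artifact
## injection, and cohort-level ground truth.

## Evaluate an expression under a fixed seed without disturbing the
## caller's RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

## Deterministic per-subject-visit sub-seed (kept well below 2^31).
recordingSeed <- function(seed, subject, visit) {
  (as.integer(seed) %% 1000000L) * 1000L + subject * 7L + visit
}

#' Unit-variance 1/f ("pink") noise
#'
#' Spectral shaping of white Gaussian noise: amplitude proportional to
#' 1/sqrt(f), flattened below 0.5 Hz to keep the variance finite, then
#' standardized to unit variance.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @return numeric vector of length `n`, sd 1.
#' @export
pinkNoise <- function(n, fs) {
  n2 <- stats::nextn(n, c(2, 3, 5))
  f <- c(0, seq_len(n2 - 1)) * fs / n2
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 0.5))
  shape[1] <- 0                              # no DC
  z <- stats::fft(stats::rnorm(n2)) * shape
  x <- Re(stats::fft(z, inverse = TRUE))[seq_len(n)] / n2
  x / stats::sd(x)
}

## Trial schedule, look-away flags and artifact draws for one
## subject-visit.  Event onsets are snapped to the decimation grid so that
## downsampling to 512 Hz is sample-exact.
planRecording <- function(config, subject, visit,
                          seed = recordingSeed(config@seed, subject, visit)) {
  withSeed(seed, {
    fs <- config@sampleRate
    R <- as.integer(fs / 512)
    nTrials <- 2L * config@nTrialsPerCondition
    bs <- nTrials / config@nBlocks
    ## balanced conditions within each block, randomized order
    condition <- character(0)
    pool <- c(face = config@nTrialsPerCondition,
              house = config@nTrialsPerCondition)
    for (b in seq_len(config@nBlocks)) {
      nf <- min(pool["face"], ceiling(bs / 2))
      nh <- bs - nf
      blockConds <- sample(c(rep("face", nf), rep("house", nh)))
      pool <- pool - c(face = nf, house = nh)
      condition <- c(condition, blockConds)
    }
    block <- rep(seq_len(config@nBlocks), each = bs)
    ## onsets: 2 s lead-in, trialDuration + jittered ISI between trials
    durSmp <- round(config@trialDuration / 1000 * fs)
    isiMs <- stats::runif(nTrials, config@isiRange[1], config@isiRange[2])
    gaps <- durSmp + round(isiMs / 1000 * fs)
    onset <- 1L + R * round((2 * fs + cumsum(c(0, gaps[-nTrials]))) / R)
    lookaway <- stats::runif(nTrials) < config@lookawayRate
    ## artifact draws per trial x electrode
    nCh <- length(config@channels)
    hit <- which(matrix(stats::runif(nTrials * nCh) < config@artifactRate,
                        nTrials, nCh), arr.ind = TRUE)
    artifacts <- data.frame(trial = integer(0), channel = character(0),
                            kind = character(0), startMs = numeric(0),
                            sign = numeric(0))
    if (nrow(hit)) {
      kind <- sample(c("spike", "flatline", "step"), nrow(hit), replace = TRUE)
      startMs <- ifelse(kind == "spike", stats::runif(nrow(hit), 0, 540),
                 ifelse(kind == "flatline", stats::runif(nrow(hit), 0, 150),
                        stats::runif(nrow(hit), 50, 400)))
      artifacts <- data.frame(trial = hit[, 1],
                              channel = config@channels[hit[, 2]],
                              kind = kind, startMs = startMs,
                              sign = sample(c(-1, 1), nrow(hit), replace = TRUE))
    }
    noiseSeed <- sample.int(.Machine$integer.max - 1L, 1L)
    list(subject = subject, visit = visit, fs = fs,
         events = data.frame(onset = as.integer(onset),
                             condition = condition, block = block,
                             lookaway = lookaway,
                             stringsAsFactors = FALSE),
         artifacts = artifacts,
         nSamples = as.integer(max(onset) + round(1.2 * fs) + 2 * fs),
         noiseSeed = noiseSeed)
  })
}

## Render a planned recording: template signal + noise + injected
## artifacts.  `amplitudes` is a list with elements `face` and `house`,
## each a named bump-amplitude vector over the five components.
renderRecording <- function(plan, templates, amplitudes, config) {
  fs <- plan$fs
  nCh <- length(config@channels)
  n <- plan$nSamples
  dat <- matrix(0, nCh, n, dimnames = list(config@channels, NULL))
  if (config@noiseSd > 0) {
    withSeed(plan$noiseSeed, {
      pf <- config@pinkNoiseFraction
      for (ch in seq_len(nCh)) {
        x <- 0
        if (pf > 0) x <- sqrt(pf) * pinkNoise(n, fs)
        if (pf < 1) x <- x + sqrt(1 - pf) * stats::rnorm(n)
        dat[ch, ] <- config@noiseSd * x
      }
    })
  }
  ## stimulus-locked template signal, rendered once per condition
  L <- round(1.2 * fs)
  tMs <- (0:L) / fs * 1000
  sig <- lapply(amplitudes, function(a)
    renderTemplateEpoch(templates, amplitudes = a, times = tMs))
  for (tr in seq_len(nrow(plan$events))) {
    i0 <- plan$events$onset[tr]
    idx <- i0:(i0 + L)
    dat[, idx] <- dat[, idx] + sig[[plan$events$condition[tr]]]
  }
  ## artifacts: magnitudes chosen to remain unambiguously flaggable after
  ## the 0.1-30 Hz zero-phase analysis filter
  if (nrow(plan$artifacts)) {
    for (i in seq_len(nrow(plan$artifacts))) {
      a <- plan$artifacts[i, ]
      ch <- match(a$channel, config@channels)
      i0 <- plan$events$onset[a$trial] + round(a$startMs / 1000 * fs)
      if (a$kind == "spike") {          # 60 ms pulse, peak 250 uV
        k <- 0:round(0.06 * fs)
        pulse <- a$sign * 250 * 0.5 * (1 - cos(2 * pi * k / max(k)))
        dat[ch, i0 + k] <- dat[ch, i0 + k] + pulse
      } else if (a$kind == "flatline") {  # 450 ms constant
        idx <- i0:(i0 + round(0.45 * fs))
        dat[ch, idx] <- dat[ch, idx[1]]
      } else {                            # step: 400 uV offset to trial end
        idx <- i0:(plan$events$onset[a$trial] + round(1.0 * fs))
        dat[ch, idx] <- dat[ch, idx] + 400
      }
    }
  }
  new("RawRecording", subject = plan$subject, visit = as.integer(plan$visit),
      sampleRate = fs, channels = config@channels, data = dat,
      events = plan$events)
}

#' Simulate one raw EEG recording
#'
#' Renders a continuous multi-channel trace for one subject-visit: the
#' planned trial sequence (balanced conditions per block, jittered ISI),
#' Gaussian component templates at the requested windowed-mean targets,
#' 1/f-plus-white noise, injected artifacts and look-away flags.  Fully
#' deterministic given `seed`.
#'
#' @param config a [CohortConfig-class].
#' @param templates a `templateSet`; built from `config` when `NULL`.
#' @param subject subject identifier.
#' @param visit visit index (1 or 2).
#' @param targets optional list with named windowed-mean target vectors
#'   `face` and `house` (uV per component); defaults to the template set's
#'   group means for `visit`.
#' @param seed integer seed for this recording.
#' @return a [RawRecording-class].
#' @examples
#' cfg <- cohortConfig(nSubjects = 1, sampleRate = 512, seed = 3)
#' rec <- simulateRecording(cfg, subject = "s01", visit = 1)
#' @export
simulateRecording <- function(config, templates = NULL, subject = "s01",
                              visit = 1, targets = NULL,
                              seed = recordingSeed(config@seed,
                                                   1L, as.integer(visit))) {
  if (is.null(templates)) templates <- buildTemplates(config)
  if (is.null(targets)) {
    amplitudes <- list(face = templates$amplitudes[[paste("face", visit)]],
                       house = templates$amplitudes[[paste("house", visit)]])
  } else {
    amplitudes <- lapply(targets, function(t) templateAmplitudes(templates, t))
  }
  plan <- planRecording(config, subject, as.integer(visit), seed = seed)
  renderRecording(plan, templates, amplitudes, config)
}

#' Draw subject-level true face-house differences
#'
#' Samples each subject's true difference score per component at both
#' visits from the bivariate normal given by an effect specification
#' (per-visit mean and SD, between-visit correlation).  Zero SDs are
#' legitimate degenerate inputs.
#'
#' @param effects data.frame as [defaultEffectSpec()].
#' @param nSubjects number of subjects.
#' @return data.frame `subject`, `component`, `visit`, `trueDiff` (uV).
#' @export
drawDifferences <- function(effects, nSubjects) {
  validateEffectSpec(effects)
  comps <- unique(effects$component)
  out <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    e1 <- effects[effects$component == comps[i] & effects$visit == 1, ]
    e2 <- effects[effects$component == comps[i] & effects$visit == 2, ]
    rho <- e1$visitCor[1]
    z1 <- stats::rnorm(nSubjects)
    z2 <- stats::rnorm(nSubjects)
    d1 <- e1$diffMean + e1$diffSd * z1
    d2 <- e2$diffMean + e2$diffSd * (rho * z1 + sqrt(1 - rho^2) * z2)
    out[[i]] <- data.frame(
      subject = rep(sprintf("s%02d", seq_len(nSubjects)), 2),
      component = comps[i],
      visit = rep(1:2, each = nSubjects),
      trueDiff = c(d1, d2), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a longitudinal synthetic cohort with ground truth
#'
#' Draws subject-level true face-house differences for every scored
#' component (P1, N290, P400, Nc) from the effect specification, converts
#' them to per-subject windowed-mean targets around the group means
#' (half the deviation added to the face target, half subtracted from the
#' house target, so the face-house difference equals the drawn value), and
#' prepares a deterministic recording plan for every subject-visit.
#'
#' Recordings are rendered lazily through the returned `recording(subject,
#' visit)` function so that cohorts of realistic size never hold all traces
#' in memory; `materialize = TRUE` renders them up front (small cohorts
#' only).
#'
#' @param config a [CohortConfig-class].
#' @param effects effect specification, see [defaultEffectSpec()].
#' @param groupMeans group-level windowed-mean targets, see
#'   [defaultGroupMeans()].
#' @param materialize render all recordings immediately.
#' @return an object of class `erpCohort`: the configuration, template set,
#'   a `groundTruth` list (`means`, `differences`, `trials`, `artifacts`
#'   data.frames), and the `recording` accessor.
#' @examples
#' coh <- generateCohort(cohortConfig(nSubjects = 2, sampleRate = 512))
#' head(coh$groundTruth$differences)
#' @export
generateCohort <- function(config, effects = defaultEffectSpec(),
                           groupMeans = defaultGroupMeans(),
                           materialize = FALSE) {
  validObject(config)
  templates <- buildTemplates(config, groupMeans)
  n <- config@nSubjects
  subjects <- sprintf("s%02d", seq_len(n))

  diffs <- withSeed(config@seed, drawDifferences(effects, n))
  diffs$trueState <- as.character(classifyState(diffs$trueDiff))

  ## per-subject windowed-mean targets (uV): group cell mean +/- half the
  ## subject's deviation from the population difference mean
  gm <- templates$groupMeans
  meansList <- vector("list", 0L)
  plans <- list()
  targets <- list()
  for (v in 1:2) {
    for (cond in c("face", "house")) {
      rows <- gm$condition == cond & gm$visit == v
      cell <- gm$mean[rows]
      names(cell) <- gm$component[rows]
      dsub <- diffs[diffs$visit == v, ]
      mu <- effects$diffMean[match(paste(dsub$component, v),
                                   paste(effects$component, effects$visit))]
      half <- (dsub$trueDiff - mu) / 2 * if (cond == "face") 1 else -1
      tm <- data.frame(subject = dsub$subject, visit = v,
                       component = dsub$component, condition = cond,
                       trueMean = cell[dsub$component] + half,
                       stringsAsFactors = FALSE)
      meansList[[paste(cond, v)]] <- tm
      for (s in seq_len(n)) {
        tgt <- cell
        rows2 <- tm$subject == subjects[s]
        tgt[tm$component[rows2]] <- tm$trueMean[rows2]
        targets[[paste(subjects[s], v, cond)]] <- tgt
      }
    }
    for (s in seq_len(n))
      plans[[paste(subjects[s], v)]] <-
        planRecording(config, subjects[s], v,
                      seed = recordingSeed(config@seed, s, v))
  }
  truthMeans <- do.call(rbind, meansList)
  rownames(truthMeans) <- NULL

  trials <- do.call(rbind, lapply(plans, function(p)
    cbind(subject = p$subject, visit = p$visit,
          trial = seq_len(nrow(p$events)), p$events)))
  rownames(trials) <- NULL
  arts <- do.call(rbind, lapply(plans, function(p)
    if (nrow(p$artifacts))
      cbind(subject = p$subject, visit = p$visit, p$artifacts)))
  if (is.null(arts))
    arts <- data.frame(subject = character(0), visit = integer(0),
                       trial = integer(0), channel = character(0),
                       kind = character(0), startMs = numeric(0),
                       sign = numeric(0))
  rownames(arts) <- NULL

  recording <- function(subject, visit) {
    key <- paste(subject, visit)
    if (is.null(plans[[key]])) stop("unknown subject-visit: ", key)
    amplitudes <- list(
      face = templateAmplitudes(templates, targets[[paste(subject, visit, "face")]]),
      house = templateAmplitudes(templates, targets[[paste(subject, visit, "house")]]))
    renderRecording(plans[[key]], templates, amplitudes, config)
  }

  out <- structure(list(
    config = config, templates = templates, subjects = subjects,
    groundTruth = list(means = truthMeans,
                       differences = diffs[, c("subject", "component",
                                               "visit", "trueDiff",
                                               "trueState")],
                       trials = trials, artifacts = arts),
    recording = recording), class = "erpCohort")
  if (materialize) {
    out$recordings <- list()
    for (v in 1:2) for (s in subjects)
      out$recordings[[paste(s, v)]] <- recording(s, v)
  }
  out
}

#' @export
print.erpCohort <- function(x, ...) {
  cat(sprintf("erpCohort: %d subjects x 2 visits (%d trials each), seed %d\n",
              x$config@nSubjects, 2L * x$config@nTrialsPerCondition,
              x$config@seed))
  st <- table(x$groundTruth$differences$component,
              x$groundTruth$differences$trueState)
  print(st)
  invisible(x)
}
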