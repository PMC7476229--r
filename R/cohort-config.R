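#' Construct a cohort simulation configuration
#'
#' Defaults reproduce the study conditions the generator emulates: 80
#' infants seen at two visits, 48 face and 48 house trials presented in 4
#' blocks of 24 (every stimulus identity once per block), 1000 ms trials
#' with a 700-1000 ms jittered inter-stimulus interval, a 32-channel 10-20
#' montage recorded at 2048 Hz.  Noise and contamination defaults are
#' generator assumptions chosen to emulate infant EEG: 15 uV total noise of
#' which 70 percent of the variance is 1/f, a 2 percent per-trial-electrode
#' artifact rate, and a 35 percent look-away rate (which reproduces the
#' roughly 30 included trials per condition typical of infant testing).
#'
#' @param nSubjects,nTrialsPerCondition,nBlocks task structure.
#' @param trialDuration,isiRange stimulus timing in ms.
#' @param sampleRate acquisition rate in Hz (multiple of 512; use 512 to
#'   skip downsampling in fast runs).
#' @param channels montage labels.
#' @param noiseSd,pinkNoiseFraction noise model.
#' @param artifactRate,lookawayRate contamination probabilities.
#' @param seed integer master seed.
#' @return a validated [CohortConfig-class] object.
#' @examples
#' cohortConfig(nSubjects = 4, sampleRate = 512, seed = 7)
#' @export
cohortConfig <- function(nSubjects = 80,
                         nTrialsPerCondition = 48,
                         nBlocks = 4,
                         trialDuration = 1000,
                         isiRange = c(700, 1000),
                         sampleRate = 2048,
                         channels = biosemi32Montage(),
                         noiseSd = 15,
                         pinkNoiseFraction = 0.7,
                         artifactRate = 0.02,
                         lookawayRate = 0.35,
                         seed = 1L) {
  new("CohortConfig",
      nSubjects = as.integer(nSubjects),
      nTrialsPerCondition = as.integer(nTrialsPerCondition),
      nBlocks = as.integer(nBlocks),
      trialDuration = as.numeric(trialDuration),
      isiRange = as.numeric(isiRange),
      sampleRate = as.numeric(sampleRate),
      channels = channels,
      noiseSd = as.numeric(noiseSd),
      pinkNoiseFraction = as.numeric(pinkNoiseFraction),
      artifactRate = as.numeric(artifactRate),
      lookawayRate = as.numeric(lookawayRate),
      seed = as.integer(seed))
}

#' Default group-mean window amplitudes
#'
#' Target windowed mean amplitudes (uV) per component, condition and visit
#' used by the template builder.  Values follow the group means reported for
#' a large longitudinal infant face/house cohort: P1 faces 7.65 / houses
#' 10.5 uV (no visit change), N290 faces 7.31 / houses 16.6 uV with a visit
#' increase (9.60 at visit 1, 14.3 at visit 2, additively combined), P400
#' faces 17.0 / houses 26.8 uV with a visit increase (17.9 to 25.9), Nc
#' faces -8.50 / houses -11.3 uV with a visit increase in magnitude (-8.05
#' to -11.7), and an N80 trough of about -3.5 uV in both conditions
#' (implied by the P1 peak-to-trough means).  Stimulus and visit effects
#' are combined additively (no interaction), matching the reported absence
#' of stimulus-by-visit interactions.
#'
#' @return data.frame with columns `component`, `condition`, `visit`,
#'   `mean` (uV).
#' @export
defaultGroupMeans <- function() {
  g <- expand.grid(component = c("N80", "P1", "N290", "P400", "Nc"),
                   condition = c("face", "house"),
                   visit = 1:2,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(g$component, g$condition, g$visit)
  val <- c(
    "N80 face 1" = -3.56, "N80 face 2" = -3.56,
    "N80 house 1" = -3.53, "N80 house 2" = -3.53,
    "P1 face 1" = 7.65, "P1 face 2" = 7.65,
    "P1 house 1" = 10.5, "P1 house 2" = 10.5,
    "N290 face 1" = 4.96, "N290 face 2" = 9.66,
    "N290 house 1" = 14.25, "N290 house 2" = 18.95,
    "P400 face 1" = 13.0, "P400 face 2" = 21.0,
    "P400 house 1" = 22.8, "P400 house 2" = 30.8,
    "Nc face 1" = -6.675, "Nc face 2" = -10.325,
    "Nc house 1" = -9.475, "Nc house 2" = -13.125)
  g$mean <- unname(val[key])
  g
}

#' Default population effect specification
#'
#' Population distribution of the subject-level face-house difference score
#' (uV) per component and visit, plus the between-visit correlation of a
#' subject's difference.  Difference means are the face minus house group
#' means of [defaultGroupMeans()]; standard deviations are set to the
#' marginal spread implied by the reported three-state subgroup summaries
#' (P1 7.0, N290 6.9, P400 8.5, Nc 5.6 uV, equal across visits, consistent
#' with the reported variance homogeneity between visits); the between-visit
#' correlation defaults to 0.5, a moderate test-retest reliability typical
#' of infant ERP difference scores.
#'
#' @return data.frame with columns `component`, `visit`, `diffMean`,
#'   `diffSd`, `visitCor`.
#' @export
defaultEffectSpec <- function() {
  comp <- c("P1", "N290", "P400", "Nc")
  data.frame(
    component = rep(comp, each = 2),
    visit = rep(1:2, times = 4),
    diffMean = rep(c(-2.85, -9.29, -9.8, 2.8), each = 2),
    diffSd = rep(c(7.0, 6.9, 8.5, 5.6), each = 2),
    visitCor = 0.5,
    stringsAsFactors = FALSE)
}

validateEffectSpec <- function(effects) {
  need <- c("component", "visit", "diffMean", "diffSd", "visitCor")
  miss <- setdiff(need, names(effects))
  if (length(miss))
    stop("effect spec is missing columns: ", paste(miss, collapse = ", "))
  if (any(effects$diffSd < 0))
    stop("effect spec standard deviations must be non-negative")
  if (any(abs(effects$visitCor) > 1))
    stop("between-visit correlation must lie in [-1, 1]")
  invisible(effects)
}
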