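#' 32-channel 10-20 montage
#'
#' Electrode labels of the 32-channel BioSemi-style cap used throughout:
#' 28 lateral channels (Fp1/2, AF3/4, F7/8, F3/4, FC1/2, FC5/6, T7/8, C3/4,
#' CP1/2, CP5/6, P7/8, P3/4, PO3/4, O1/2) and 4 midline channels (Fz, Cz,
#' Pz, Oz).
#'
#' @return character vector of 32 channel labels.
#' @export
biosemi32Montage <- function() {
  c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "PO3", "PO4", "O1", "Oz", "O2")
}

#' ERP component definitions
#'
#' Time windows, critical electrode sets, polarity and preceding-component
#' chain for the infant face-processing components:
#'
#' * `N80`: 70-90 ms, occipital, negative -- the small trough preceding P1.
#' * `P1`: 90-180 ms over PO3, O1, Oz, O2, PO4, positive.
#' * `N290`: 170-300 ms over P3, PO3, O1, Oz, O2, PO4, P4, negative.
#' * `P400`: 300-500 ms over the same seven electrodes, positive.
#' * `Nc`: 300-600 ms over Fz, C3, C4, negative.
#'
#' `latencyConditions` lists the conditions for which a peak latency is a
#' supported measure (P1: both; N290: faces only -- house waveforms show no
#' clear trough; others: none).  `family` groups components under the
#' trial-count inclusion rule (N290 and P400 share electrodes and hence a
#' family).
#'
#' @return named list of component definitions; each element is a list with
#'   fields `name`, `window` (ms pair), `electrodes`, `polarity`,
#'   `preceding`, `latencyConditions`, `family`.
#' @export
componentDefinitions <- function() {
  p1set <- c("PO3", "O1", "Oz", "O2", "PO4")
  n290set <- c("P3", "PO3", "O1", "Oz", "O2", "PO4", "P4")
  ncset <- c("Fz", "C3", "C4")
  list(
    N80 = list(name = "N80", window = c(70, 90), electrodes = p1set,
               polarity = "negative", preceding = NA_character_,
               latencyConditions = character(), family = "P1"),
    P1 = list(name = "P1", window = c(90, 180), electrodes = p1set,
              polarity = "positive", preceding = "N80",
              latencyConditions = c("face", "house"), family = "P1"),
    N290 = list(name = "N290", window = c(170, 300), electrodes = n290set,
                polarity = "negative", preceding = "P1",
                latencyConditions = "face", family = "N290P400"),
    P400 = list(name = "P400", window = c(300, 500), electrodes = n290set,
                polarity = "positive", preceding = "N290",
                latencyConditions = character(), family = "N290P400"),
    Nc = list(name = "Nc", window = c(300, 600), electrodes = ncset,
              polarity = "negative", preceding = NA_character_,
              latencyConditions = character(), family = "Nc")
  )
}

#' Critical electrodes per component family
#'
#' The electrodes whose artifact-free trial counts decide whether a
#' subject-visit is included for a component family's analyses.
#'
#' @return named list of electrode label vectors for families `P1`,
#'   `N290P400` and `Nc`.
#' @export
criticalElectrodes <- function() {
  defs <- componentDefinitions()
  list(P1 = defs$P1$electrodes,
       N290P400 = defs$N290$electrodes,
       Nc = defs$Nc$electrodes)
}

## Components that get a scored mean amplitude / difference score.
scoredComponents <- function() c("P1", "N290", "P400", "Nc")

## Closed-window sample selector: start <= t <= end.
windowIndex <- function(times, window) {
  which(times >= window[1] & times <= window[2])
}
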