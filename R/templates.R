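## Component waveform templates: Gaussian bumps in time, constant across a
## component's electrode set, scaled so that the noise-free rendering has a
## prescribed windowed mean amplitude on that set.

#' Epoch time axis at the analysis rate
#'
#' Samples run from 200 ms pre-stimulus to 1000 ms post-stimulus on the
#' sampling grid: `round(0.2 * fs)` samples before onset, `fs` samples
#' after, so at 512 Hz the axis is -199.2 to 1000 ms in steps of ~1.95 ms
#' with t = 0 at stimulus onset.
#'
#' @param fs analysis sampling rate in Hz.
#' @return numeric vector of times in ms.
#' @export
analysisTimes <- function(fs = 512) {
  (-round(0.2 * fs):round(1.0 * fs)) / fs * 1000
}

## Gaussian bump centres and widths (ms).  Centres sit at the canonical
## infant peak latencies (P1 ~135 ms, N290 ~235 ms); widths are chosen so
## each bump is confined to the vicinity of its window while staying well
## inside the 30 Hz pass-band of the analysis filter.
templateShapeDefaults <- function() {
  data.frame(component = c("N80", "P1", "N290", "P400", "Nc"),
             center = c(80, 135, 235, 400, 450),
             width = c(12, 22, 38, 55, 80),
             stringsAsFactors = FALSE)
}

#' Build component templates with prescribed windowed means
#'
#' Constructs one Gaussian template per component (N80, P1, N290, P400, Nc)
#' whose superposition, rendered noise-free on the analysis grid, has
#' windowed mean amplitude equal to the requested group mean on each
#' component's electrode set.  Because neighbouring components leak into
#' each other's windows, the per-component amplitudes are obtained by
#' solving the (small) linear system that maps bump amplitudes to windowed
#' means.
#'
#' With `compensate = TRUE` (default) each template additionally carries a
#' uniform opposite-sign offset on the electrodes outside its set so that
#' the instantaneous mean across the full montage is zero; the rendered
#' signal is then invariant under common-average referencing and the
#' requested windowed means survive the full preprocessing chain.  With
#' `compensate = FALSE` non-member electrodes receive zero signal.
#'
#' @param config a [CohortConfig-class]; supplies the montage.
#' @param groupMeans data.frame as [defaultGroupMeans()]: requested
#'   windowed mean (uV) per component, condition and visit.
#' @param shapes data.frame of bump `center` and `width` (ms) per
#'   component; defaults to canonical infant latencies.
#' @param compensate zero-sum compensation on non-member electrodes.
#' @return an object of class `templateSet`: component shapes, electrode
#'   weight matrix, solved amplitudes per condition and visit, and the
#'   inverse design matrix used to re-solve amplitudes for subject-level
#'   targets.
#' @examples
#' ts <- buildTemplates(cohortConfig(sampleRate = 512))
#' ep <- renderTemplateEpoch(ts, "face", 1)
#' @export
buildTemplates <- function(config, groupMeans = defaultGroupMeans(),
                           shapes = templateShapeDefaults(),
                           compensate = TRUE) {
  defs <- componentDefinitions()
  comps <- names(defs)
  channels <- config@channels
  times <- analysisTimes(512)
  for (d in defs) {
    bad <- setdiff(d$electrodes, channels)
    if (length(bad))
      stop("unknown electrode label(s) for ", d$name, ": ",
           paste(bad, collapse = ", "))
    if (d$window[1] < min(times) || d$window[2] > max(times))
      stop("window for ", d$name, " lies outside the epoch span")
  }
  if (!all(comps %in% shapes$component))
    stop("shapes must cover all components")
  shapes <- shapes[match(comps, shapes$component), ]
  if (any(shapes$width <= 0)) stop("template widths must be positive")

  nCh <- length(channels)
  ## electrode weights: 1 on the component's set, compensating negative
  ## offset elsewhere (zero-sum across the montage), or 0 if uncompensated
  W <- matrix(0, length(comps), nCh, dimnames = list(comps, channels))
  for (k in comps) {
    member <- channels %in% defs[[k]]$electrodes
    m <- sum(member)
    W[k, member] <- 1
    if (compensate) W[k, !member] <- -m / (nCh - m)
  }
  ## Gaussian bumps evaluated on the analysis grid
  G <- vapply(seq_along(comps), function(k)
    exp(-(times - shapes$center[k])^2 / (2 * shapes$width[k]^2)),
    numeric(length(times)))
  colnames(G) <- comps
  ## design matrix: windowed mean of component k's template over component
  ## j's window and electrode set
  M <- matrix(0, length(comps), length(comps), dimnames = list(comps, comps))
  for (j in comps) {
    idx <- windowIndex(times, defs[[j]]$window)
    sj <- channels %in% defs[[j]]$electrodes
    for (k in comps)
      M[j, k] <- mean(G[idx, k]) * mean(W[k, sj])
  }
  Minv <- solve(M)

  ## group-level amplitudes per condition x visit
  amplitudes <- list()
  for (cond in c("face", "house")) for (v in 1:2) {
    rows <- groupMeans$condition == cond & groupMeans$visit == v
    tgt <- groupMeans$mean[rows][match(comps, groupMeans$component[rows])]
    if (anyNA(tgt))
      stop("groupMeans must supply every component for ", cond, " visit ", v)
    amplitudes[[paste(cond, v)]] <- drop(Minv %*% tgt)
  }
  structure(list(components = comps, shapes = shapes, channels = channels,
                 weights = W, times = times, Minv = Minv,
                 amplitudes = amplitudes, groupMeans = groupMeans,
                 compensate = compensate),
            class = "templateSet")
}

#' Solve template amplitudes for arbitrary windowed-mean targets
#'
#' @param templates a `templateSet` from [buildTemplates()].
#' @param targets named numeric vector of requested windowed means (uV),
#'   one per component.
#' @return named numeric vector of bump amplitudes.
#' @export
templateAmplitudes <- function(templates, targets) {
  tgt <- targets[templates$components]
  if (anyNA(tgt)) stop("targets must name every component")
  drop(templates$Minv %*% tgt)
}

#' Render a noise-free template epoch
#'
#' @param templates a `templateSet`.
#' @param condition,visit which group-level amplitude set to render.
#' @param amplitudes optional explicit amplitude vector (overrides
#'   `condition`/`visit`), e.g. from [templateAmplitudes()].
#' @param times time axis in ms (defaults to the 512 Hz analysis grid).
#' @return channels x time matrix in uV.
#' @export
renderTemplateEpoch <- function(templates, condition = "face", visit = 1,
                                amplitudes = NULL, times = templates$times) {
  if (is.null(amplitudes))
    amplitudes <- templates$amplitudes[[paste(condition, visit)]]
  G <- vapply(seq_along(templates$components), function(k)
    exp(-(times - templates$shapes$center[k])^2 /
          (2 * templates$shapes$width[k]^2)),
    numeric(length(times)))
  out <- crossprod(templates$weights, amplitudes * t(G))
  dimnames(out) <- list(templates$channels, NULL)
  out
}

#' Windowed mean amplitude of a waveform matrix
#'
#' Arithmetic mean over the closed time window, then over the named
#' electrodes -- the elementary measure used throughout component scoring.
#'
#' @param mat channels x time matrix.
#' @param times time axis in ms.
#' @param window ms pair, closed interval.
#' @param electrodes electrode labels (must be row names or match
#'   `channels`).
#' @param channels channel labels for the rows of `mat`.
#' @return mean amplitude in uV.
#' @export
windowedMean <- function(mat, times, window, electrodes,
                         channels = rownames(mat)) {
  idx <- windowIndex(times, window)
  rows <- match(electrodes, channels)
  if (anyNA(rows)) stop("electrode labels not present in waveform")
  mean(mat[rows, idx, drop = FALSE])
}
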