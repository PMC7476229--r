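## Component scoring: windowed mean amplitude, peak latency,
## peak-to-trough corrected amplitude, and face-house difference scores.

componentDef <- function(component, defs = componentDefinitions()) {
  d <- defs[[component]]
  if (is.null(d)) stop("unknown component: ", component)
  d
}

erpMatrix <- function(erp, condition) {
  condition <- match.arg(condition, c("face", "house"))
  erp@waveforms[[condition]]
}

#' Mean amplitude of a component
#'
#' Arithmetic mean over the component's closed time window, then over its
#' critical electrodes.  Returns `NA` when a critical electrode is
#' rejected (the subject's exclusion propagates).
#'
#' @param erp a [SubjectERP-class].
#' @param component component name (`"N80"`, `"P1"`, `"N290"`, `"P400"`,
#'   `"Nc"`).
#' @param condition `"face"` or `"house"`.
#' @param defs component definitions, see [componentDefinitions()].
#' @return mean amplitude in uV, or `NA`.
#' @export
meanAmplitude <- function(erp, component, condition,
                          defs = componentDefinitions()) {
  d <- componentDef(component, defs)
  mat <- erpMatrix(erp, condition)
  rows <- match(d$electrodes, erp@channels)
  if (anyNA(rows)) stop("component electrodes missing from montage")
  vals <- mat[rows, windowIndex(erp@times, d$window), drop = FALSE]
  if (anyNA(vals)) return(NA_real_)
  mean(vals)
}

#' Peak latency of a component
#'
#' Per critical electrode, the time of the extreme sample within the
#' component window (maximum for positive components, minimum for
#' negative), averaged across electrodes.  Ties are broken by the earliest
#' sample; an all-tied (flat) window returns the window start with a
#' `lowConfidence` attribute.  Latency is only supported where a peak is
#' reliably identifiable (P1 for both conditions, N290 for faces);
#' requesting any other combination signals a classed error
#' (`"infantERP_unsupportedMeasure"`).
#'
#' @inheritParams meanAmplitude
#' @return latency in ms (on the sampling grid), or `NA` when a critical
#'   electrode is rejected.
#' @export
peakLatency <- function(erp, component, condition,
                        defs = componentDefinitions()) {
  d <- componentDef(component, defs)
  condition <- match.arg(condition, c("face", "house"))
  if (!condition %in% d$latencyConditions)
    stop(errorCondition(
      sprintf("peak latency of %s is not a supported measure for %s trials (no reliable peak)",
              component, condition),
      class = c("infantERP_unsupportedMeasure", "error")))
  mat <- erpMatrix(erp, condition)
  rows <- match(d$electrodes, erp@channels)
  idx <- windowIndex(erp@times, d$window)
  seg <- mat[rows, idx, drop = FALSE]
  if (anyNA(seg)) return(NA_real_)
  pick <- if (d$polarity == "positive") max.col(seg, ties.method = "first")
          else max.col(-seg, ties.method = "first")
  flat <- apply(seg, 1, function(x) max(x) == min(x))
  lat <- mean(erp@times[idx][pick])
  if (any(flat)) attr(lat, "lowConfidence") <- TRUE
  lat
}

#' Peak-to-trough corrected amplitude
#'
#' The component's windowed mean amplitude minus the "peak" of its
#' preceding component, removing carry-over from the preceding deflection:
#'
#' * `P1`: mean(90-180 ms) minus the N80 mean amplitude (70-90 ms) -- the
#'   preceding trough is scored as a windowed mean, not an extreme sample;
#' * `N290`: mean(170-300 ms) minus the per-electrode most positive sample
#'   in 90-180 ms, averaged across electrodes;
#' * `P400`: mean(300-500 ms) minus the per-electrode most negative sample
#'   in 170-300 ms, averaged across electrodes.
#'
#' The preceding peak is evaluated on the current component's electrode
#' set by default (`precedingOn = "current"`), so that the subtraction is
#' computed over matched electrodes; `precedingOn = "preceding"` uses the
#' preceding component's own set instead.
#'
#' @inheritParams meanAmplitude
#' @param precedingOn electrode set hosting the preceding-peak evaluation.
#' @return corrected amplitude in uV, or `NA` when required electrodes are
#'   rejected.
#' @export
peakToTrough <- function(erp, component, condition,
                         defs = componentDefinitions(),
                         precedingOn = c("current", "preceding")) {
  precedingOn <- match.arg(precedingOn)
  if (!component %in% c("P1", "N290", "P400"))
    stop("peak-to-trough is defined for P1, N290 and P400 only")
  d <- componentDef(component, defs)
  pd <- componentDef(d$preceding, defs)
  own <- meanAmplitude(erp, component, condition, defs)
  if (is.na(own)) return(NA_real_)
  electrodes <- if (precedingOn == "current") d$electrodes else pd$electrodes
  mat <- erpMatrix(erp, condition)
  rows <- match(electrodes, erp@channels)
  idx <- windowIndex(erp@times, pd$window)
  seg <- mat[rows, idx, drop = FALSE]
  if (anyNA(seg)) return(NA_real_)
  prec <- if (component == "P1") {
    mean(seg)                                  # N80 is a windowed mean
  } else if (pd$polarity == "positive") {
    mean(apply(seg, 1, max))
  } else {
    mean(apply(seg, 1, min))
  }
  own - prec
}

#' Face-house difference score
#'
#' @param face,house mean amplitudes (uV) for the two conditions of the
#'   same subject, visit and component.
#' @return `face - house` in uV (`NA` if either side is absent).
#' @export
differenceScore <- function(face, house) face - house

#' Score all components for a set of subject ERPs
#'
#' Produces the tidy long-format scores table that feeds the trajectory
#' and statistics modules: one row per subject, visit, component,
#' condition and measure.  Measures are `mean_amplitude` (all four scored
#' components), `peak_to_trough` (P1, N290, P400) and `peak_latency` (P1
#' both conditions, N290 faces).  Scores for component families in which a
#' subject-visit is not included (fewer than the required artifact-free
#' trials at a critical electrode) are `NA`.
#'
#' @param erps list of [SubjectERP-class] objects.
#' @param defs component definitions.
#' @return data.frame with columns `subject`, `visit`, `component`,
#'   `condition`, `measure`, `value`.
#' @export
scoreComponents <- function(erps, defs = componentDefinitions()) {
  rows <- list()
  for (erp in erps) {
    inc <- erp@inclusion
    for (comp in scoredComponents()) {
      d <- defs[[comp]]
      included <- isTRUE(inc[[d$family]])
      for (cond in c("face", "house")) {
        m <- if (included) meanAmplitude(erp, comp, cond, defs) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          subject = erp@subject, visit = erp@visit, component = comp,
          condition = cond, measure = "mean_amplitude", value = m,
          stringsAsFactors = FALSE)
        if (comp %in% c("P1", "N290", "P400")) {
          p <- if (included) peakToTrough(erp, comp, cond, defs) else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            subject = erp@subject, visit = erp@visit, component = comp,
            condition = cond, measure = "peak_to_trough", value = p,
            stringsAsFactors = FALSE)
        }
        if (cond %in% d$latencyConditions) {
          l <- if (included) as.numeric(peakLatency(erp, comp, cond, defs))
               else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            subject = erp@subject, visit = erp@visit, component = comp,
            condition = cond, measure = "peak_latency", value = l,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Face-house difference scores from a tidy scores table
#'
#' @param scores tidy table from [scoreComponents()].
#' @param measure which measure to difference (default `mean_amplitude`).
#' @return data.frame `subject`, `visit`, `component`, `value` with
#'   `value = face - house`.
#' @export
differenceScores <- function(scores, measure = "mean_amplitude") {
  s <- scores[scores$measure == measure, ]
  f <- s[s$condition == "face", ]
  h <- s[s$condition == "house", ]
  key <- function(d) paste(d$subject, d$visit, d$component)
  m <- match(key(f), key(h))
  if (anyNA(m)) stop("face/house scores are not paired")
  data.frame(subject = f$subject, visit = f$visit, component = f$component,
             value = differenceScore(f$value, h$value[m]),
             stringsAsFactors = FALSE)
}
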