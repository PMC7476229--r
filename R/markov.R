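## Three-state classification of face-house difference scores and the
## descriptive between-visit transition structure.

stateLevels <- function() c("negative", "none", "positive")

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, matching how the summary percentages
#' are conventionally printed (e.g. 82.5 percent rounds to 83).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify a difference score into a discrete state
#'
#' A difference below `-threshold` is `"negative"`, above `+threshold`
#' `"positive"`, and anything in between -- boundary values included --
#' `"none"`.  `NA` differences yield `NA` (the subject is dropped from
#' that component's transition table).
#'
#' @param value face-house difference score(s) in uV.
#' @param threshold classification threshold in uV (default 1.5).
#' @return factor with levels `negative`, `none`, `positive`.
#' @examples
#' classifyState(c(-2, -1.5, 0, 1.5, 2))
#' @export
classifyState <- function(value, threshold = 1.5) {
  stopifnot(threshold > 0)
  out <- ifelse(is.na(value), NA_character_,
         ifelse(value < -threshold, "negative",
         ifelse(value > threshold, "positive", "none")))
  factor(out, levels = stateLevels())
}

#' Build a between-visit state-transition table
#'
#' Cross-tabulates each subject's state at Visit 1 against Visit 2,
#' row-normalizes to transition probabilities, and attaches the
#' dominant-group summary.  Subjects with a missing state at either visit
#' are dropped from this component's table only.
#'
#' @param statesV1,statesV2 state factors (or difference scores, which are
#'   classified with `threshold`), one entry per subject, same order.
#' @param component component name recorded in the table.
#' @param threshold classification threshold in uV.
#' @return a [TransitionTable-class].
#' @examples
#' tab <- buildTransitionTable(c(-3, -2, 4), c(-2, 0.5, -9), "N290")
#' transitionCounts(tab)
#' @export
buildTransitionTable <- function(statesV1, statesV2, component = "",
                                 threshold = 1.5) {
  if (is.numeric(statesV1)) statesV1 <- classifyState(statesV1, threshold)
  if (is.numeric(statesV2)) statesV2 <- classifyState(statesV2, threshold)
  statesV1 <- factor(statesV1, levels = stateLevels())
  statesV2 <- factor(statesV2, levels = stateLevels())
  if (length(statesV1) != length(statesV2))
    stop("the same subjects must be classified at both visits")
  keep <- !is.na(statesV1) & !is.na(statesV2)
  if (!any(keep))
    stop(errorCondition("no classifiable subjects for this component",
                        class = c("infantERP_emptyTable", "error")))
  counts <- unclass(table(visit1 = statesV1[keep], visit2 = statesV2[keep]))
  storage.mode(counts) <- "integer"
  rs <- rowSums(counts)
  probs <- counts / rs          # rows with zero marginal become NaN
  tab <- new("TransitionTable", component = component,
             threshold = threshold, counts = counts,
             probabilities = probs, n = sum(counts), summary = list())
  tab@summary <- summarizeDominant(tab)
  validObject(tab)
  tab
}

#' Build a transition table directly from printed/stored counts
#'
#' @param counts 3 x 3 matrix, rows = Visit 1 state, columns = Visit 2
#'   state, in the order negative / none / positive.
#' @param component component name.
#' @param threshold classification threshold recorded in the table.
#' @return a [TransitionTable-class].
#' @export
transitionTableFromCounts <- function(counts, component = "",
                                      threshold = 1.5) {
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(visit1 = stateLevels(),
                                   visit2 = stateLevels()))
  probs <- counts / rowSums(counts)
  tab <- new("TransitionTable", component = component,
             threshold = threshold, counts = counts,
             probabilities = probs, n = sum(counts), summary = list())
  tab@summary <- summarizeDominant(tab)
  validObject(tab)
  tab
}

#' Dominant-group summary of a transition table
#'
#' Returns the descriptive percentages used to compare developmental
#' trajectories across components:
#'
#' * `dominant`: the modal Visit 1 state (ties are flagged and all modal
#'   states reported);
#' * `dominantShareV1`, `dominantShareV2`: share of subjects in the
#'   dominant state at each visit;
#' * `persistence`: share of Visit 1 dominant-state subjects who remain in
#'   it at Visit 2;
#' * `moverShare`: share of Visit 1 non-dominant subjects who end in the
#'   dominant state at Visit 2;
#' * `bothVisitShare`: share of all subjects in the dominant state at both
#'   visits.
#'
#' Percentages are rounded half-up to integers, except `bothVisitShare`
#' which keeps two decimals; unrounded values are returned under `raw`.
#'
#' @param tab a [TransitionTable-class].
#' @return list with the fields above plus `raw` and `tie`.
#' @export
summarizeDominant <- function(tab) {
  counts <- tab@counts
  n <- sum(counts)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  dom <- which(rs == max(rs))
  tie <- length(dom) > 1L
  d <- dom[1]
  stay <- unname(counts[d, d])
  rsd <- unname(rs[d])
  csd <- unname(cs[d])
  nonDom <- n - rsd
  movers <- csd - stay
  raw <- list(
    dominantShareV1 = 100 * rsd / n,
    dominantShareV2 = 100 * csd / n,
    persistence = if (rsd > 0) 100 * stay / rsd else NaN,
    moverShare = if (nonDom > 0) 100 * movers / nonDom else NaN,
    bothVisitShare = 100 * stay / n)
  list(dominant = stateLevels()[dom], tie = tie,
       dominantShareV1 = roundHalfUp(raw$dominantShareV1),
       dominantShareV2 = roundHalfUp(raw$dominantShareV2),
       persistence = roundHalfUp(raw$persistence),
       moverShare = roundHalfUp(raw$moverShare),
       bothVisitShare = roundHalfUp(raw$bothVisitShare, 2),
       raw = lapply(raw, unname))
}

#' Transition tables for every component of a difference-score table
#'
#' @param diffs data.frame from [differenceScores()] with both visits per
#'   subject.
#' @param threshold classification threshold in uV.
#' @return named list of [TransitionTable-class] objects, one per
#'   component present.
#' @export
transitionTables <- function(diffs, threshold = 1.5) {
  comps <- unique(diffs$component)
  out <- list()
  for (comp in comps) {
    d <- diffs[diffs$component == comp, ]
    d1 <- d[d$visit == 1, ]
    d2 <- d[d$visit == 2, ]
    m <- match(d1$subject, d2$subject)
    out[[comp]] <- buildTransitionTable(d1$value, d2$value[m],
                                        component = comp,
                                        threshold = threshold)
  }
  out
}

#' Dot-format description of a transition diagram
#'
#' @param tab a [TransitionTable-class].
#' @return character scalar with a GraphViz dot digraph of the non-zero
#'   transition probabilities (percentages on the edges).
#' @export
transitionDot <- function(tab) {
  p <- tab@probabilities
  lines <- c(sprintf("digraph %s {", gsub("[^A-Za-z0-9]", "_", tab@component)))
  rs <- rowSums(tab@counts)
  for (s in stateLevels())
    lines <- c(lines, sprintf('  %s [label="%s\\n%d"];', s, s,
                              rs[match(s, stateLevels())]))
  for (i in 1:3) for (j in 1:3)
    if (!is.nan(p[i, j]) && p[i, j] > 0)
      lines <- c(lines, sprintf('  %s -> %s [label="%s%%"];',
                                stateLevels()[i], stateLevels()[j],
                                roundHalfUp(100 * p[i, j])))
  paste(c(lines, "}"), collapse = "\n")
}
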