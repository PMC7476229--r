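## Within-subject inferential layer, implemented from first principles:
## 2x2 fully-within repeated-measures ANOVA with partial eta squared,
## paired t-test with Cohen's d, and the Brown-Forsythe test.

#' 2x2 fully-within repeated-measures ANOVA
#'
#' Stimulus (face/house) by visit (1/2) within-subject decomposition.
#' Each effect is tested against its own subject-by-effect interaction,
#' giving F(1, n-1) tests; with two-level factors sphericity is trivially
#' satisfied, so no correction is applied.  Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' Input is a long table with one row per subject x stimulus x visit cell;
#' only complete cases (subjects with all four cells) are analysed.
#'
#' @param table data.frame with columns `subject`, `stimulus`
#'   (`"face"`/`"house"`), `visit` (1/2), `value`.
#' @return object of class `rmAnova2x2`: a data.frame with one row per
#'   effect (`stimulus`, `visit`, `interaction`) and columns `F`, `df1`,
#'   `df2`, `p`, `petaSq`, plus attributes `n`, `cellMeans`, `cellSds`.
#'   A zero error sum of squares yields `F = NA` (undefined, not an
#'   error).
#' @examples
#' tbl <- expand.grid(subject = 1:6, stimulus = c("face", "house"),
#'                    visit = 1:2)
#' tbl$value <- rnorm(nrow(tbl)) + (tbl$stimulus == "face") * 2
#' rmAnova2x2(tbl)
#' @export
rmAnova2x2 <- function(table) {
  need <- c("subject", "stimulus", "visit", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table is missing columns: ", paste(miss, collapse = ", "))
  ## wide n x 4 cell matrix, complete cases only
  cells <- expand.grid(stimulus = c("face", "house"), visit = 1:2,
                       KEEP.OUT.ATTRS = FALSE)
  subjects <- unique(table$subject)
  Y <- matrix(NA_real_, length(subjects), 4)
  for (j in 1:4) {
    rows <- table$stimulus == cells$stimulus[j] & table$visit == cells$visit[j]
    m <- match(subjects, table$subject[rows])
    Y[, j] <- table$value[rows][m]
  }
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  n <- nrow(Y)
  if (n < 2L) stop("at least 2 complete-case subjects are required")

  grand <- mean(Y)
  subjMean <- rowMeans(Y)
  stimMean <- c(face = mean(Y[, c(1, 3)]), house = mean(Y[, c(2, 4)]))
  visitMean <- c(mean(Y[, 1:2]), mean(Y[, 3:4]))
  cellMean <- colMeans(Y)

  ## per-subject marginal means over the other factor
  subjStim <- cbind(rowMeans(Y[, c(1, 3)]), rowMeans(Y[, c(2, 4)]))
  subjVisit <- cbind(rowMeans(Y[, 1:2]), rowMeans(Y[, 3:4]))

  ssStim <- 2 * sum(n * (stimMean - grand)^2)
  ssVisit <- 2 * sum(n * (visitMean - grand)^2)
  ## interaction: cell deviations from additivity, n subjects per cell
  stimOf <- c(1, 2, 1, 2); visitOf <- c(1, 1, 2, 2)
  ssInter <- n * sum((cellMean - stimMean[stimOf] - visitMean[visitOf] + grand)^2)
  ## error strata
  ssStimErr <- 2 * sum((subjStim - outer(subjMean, c(1, 1)) -
                          outer(rep(1, n), stimMean) + grand)^2)
  ssVisitErr <- 2 * sum((subjVisit - outer(subjMean, c(1, 1)) -
                           outer(rep(1, n), visitMean) + grand)^2)
  resid <- Y
  for (j in 1:4)
    resid[, j] <- Y[, j] - cellMean[j] - subjStim[, stimOf[j]] -
      subjVisit[, visitOf[j]] + stimMean[stimOf[j]] + visitMean[visitOf[j]] +
      subjMean - grand
  ssInterErr <- sum(resid^2)

  mkRow <- function(ss, ssErr) {
    df2 <- n - 1L
    if (ssErr <= .Machine$double.eps * max(1, ss)) {
      c(F = NA_real_, df1 = 1, df2 = df2, p = NA_real_,
        petaSq = if (ss > 0) 1 else NA_real_)
    } else {
      Fv <- ss / (ssErr / df2)
      c(F = Fv, df1 = 1, df2 = df2,
        p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
        petaSq = ss / (ss + ssErr))
    }
  }
  out <- as.data.frame(rbind(stimulus = mkRow(ssStim, ssStimErr),
                             visit = mkRow(ssVisit, ssVisitErr),
                             interaction = mkRow(ssInter, ssInterErr)))
  out$effect <- rownames(out)
  out <- out[, c("effect", "F", "df1", "df2", "p", "petaSq")]
  rownames(out) <- NULL
  attr(out, "n") <- n
  cm <- stats::setNames(cellMean, paste(cells$stimulus, cells$visit, sep = "."))
  attr(out, "cellMeans") <- cm
  attr(out, "cellSds") <- stats::setNames(apply(Y, 2, stats::sd), names(cm))
  attr(out, "marginalMeans") <- list(
    stimulus = stimMean,
    visit = stats::setNames(visitMean, c("1", "2")))
  class(out) <- c("rmAnova2x2", "data.frame")
  out
}

#' @export
print.rmAnova2x2 <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("2x2 within-subject ANOVA (n = %d)\n", n))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$F[i]))
      cat(sprintf("  %-12s F(1,%d) undefined (zero error variance)\n",
                  x$effect[i], x$df2[i]))
    else
      cat(sprintf("  %-12s F(1,%d) = %.3g, p = %.3g, partial eta sq = %.3g\n",
                  x$effect[i], x$df2[i], x$F[i], x$p[i], x$petaSq[i]))
  }
  invisible(x)
}

#' Paired t-test with Cohen's d
#'
#' Classical paired t on `x - y`, with two-sided p and the standardized
#' mean difference `d = mean(x - y) / sd(x - y)`.
#'
#' @param x,y paired per-subject values, equal length >= 2.
#' @return list of class `pairedTTest` with `t`, `df`, `p`, `d`,
#'   `meanDiff`, `n`.  Identical pairs give `t = 0`; a zero-variance but
#'   non-zero difference yields `t = NA` (undefined) rather than an error.
#' @examples
#' pairedTTest(c(2, 3, 5), c(1, 1, 2))
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("at least 2 complete pairs are required")
  sdd <- stats::sd(d)
  md <- mean(d)
  if (sdd == 0 && md == 0) {
    ## identical pairs: no effect, not an undefined statistic
    res <- list(t = 0, df = n - 1L, p = 1, d = 0, meanDiff = 0, n = n)
  } else if (sdd == 0) {
    res <- list(t = NA_real_, df = n - 1L, p = NA_real_, d = NA_real_,
                meanDiff = md, n = n)
  } else {
    tv <- md / (sdd / sqrt(n))
    res <- list(t = tv, df = n - 1L,
                p = 2 * stats::pt(abs(tv), n - 1L, lower.tail = FALSE),
                d = md / sdd, meanDiff = md, n = n)
  }
  class(res) <- "pairedTTest"
  res
}

#' @export
print.pairedTTest <- function(x, ...) {
  if (is.na(x$t))
    cat(sprintf("paired t(%d) undefined (zero-variance differences)\n", x$df))
  else
    cat(sprintf("paired t(%d) = %.3g, p = %.3g, d = %.3g\n",
                x$df, x$t, x$p, x$d))
  invisible(x)
}

#' Brown-Forsythe test of variance homogeneity
#'
#' One-way ANOVA on the absolute deviations from the group medians.
#' Robust to non-normality; a group whose deviations are all zero is
#' legitimate input.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @return list of class `brownForsythe` with `F`, `df1`, `df2`, `p`.
#' @examples
#' brownForsythe(c(1, 2, 3, 10, 20, 30), rep(c("a", "b"), each = 3))
#' @export
brownForsythe <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("at least 2 groups are required")
  if (any(tabulate(groups) < 2L)) stop("each group needs at least 2 values")
  med <- tapply(values, groups, stats::median)
  z <- abs(values - med[groups])
  zbar <- mean(z)
  zg <- tapply(z, groups, mean)
  ng <- tabulate(groups)
  k <- nlevels(groups)
  N <- length(z)
  ssB <- sum(ng * (zg - zbar)^2)
  ssW <- sum((z - zg[groups])^2)
  df1 <- k - 1L
  df2 <- N - k
  if (ssW == 0 && ssB == 0) {
    Fv <- 0; p <- 1
  } else if (ssW == 0) {
    Fv <- Inf; p <- 0
  } else {
    Fv <- (ssB / df1) / (ssW / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = unname(Fv), df1 = df1, df2 = df2, p = unname(p)),
            class = "brownForsythe")
}

#' @export
print.brownForsythe <- function(x, ...) {
  cat(sprintf("Brown-Forsythe F(%d,%d) = %.3g, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}
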