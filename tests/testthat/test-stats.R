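randomDesign <- function(n, seed, stimEffect = 0, visitEffect = 0,
                         interEffect = 0, subjectSd = 2, noiseSd = 1) {
  set.seed(seed)
  tbl <- expand.grid(subject = seq_len(n), stimulus = c("face", "house"),
                     visit = 1:2, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  subj <- rnorm(n, sd = subjectSd)
  tbl$value <- subj[tbl$subject] +
    stimEffect * (tbl$stimulus == "face") +
    visitEffect * (tbl$visit == 2) +
    interEffect * (tbl$stimulus == "face") * (tbl$visit == 2) +
    rnorm(nrow(tbl), sd = noiseSd)
  tbl
}

aovOracle <- function(tbl) {
  d <- transform(tbl, subject = factor(subject), stimulus = factor(stimulus),
                 visit = factor(visit))
  fit <- summary(stats::aov(value ~ stimulus * visit +
                              Error(subject / (stimulus * visit)), data = d))
  get1 <- function(stratum, row) fit[[stratum]][[1]][row, ]
  list(stimulus = get1("Error: subject:stimulus", "stimulus"),
       visit = get1("Error: subject:visit", "visit"),
       interaction = get1("Error: subject:stimulus:visit", "stimulus:visit"))
}

test_that("the within-subject ANOVA matches the full aov decomposition", {
  for (seed in c(1, 2, 3)) {
    tbl <- randomDesign(n = if (seed == 1) 4 else 11, seed = seed,
                        stimEffect = 1.5, visitEffect = -1)
    fit <- rmAnova2x2(tbl)
    oracle <- aovOracle(tbl)
    for (eff in c("stimulus", "visit", "interaction")) {
      row <- fit[fit$effect == eff, ]
      expect_equal(row$F, oracle[[eff]][["F value"]], tolerance = 1e-10)
      expect_equal(row$p, oracle[[eff]][["Pr(>F)"]], tolerance = 1e-10)
      # partial eta squared from the oracle's sums of squares
      ssE <- oracle[[eff]][["Sum Sq"]]
      ssErr <- ssE / oracle[[eff]][["F value"]] * (attr(fit, "n") - 1)
      expect_equal(row$petaSq, ssE / (ssE + ssErr), tolerance = 1e-10)
      expect_equal(row$df2, attr(fit, "n") - 1)
    }
  }
})

test_that("F equals t squared for each two-level within factor", {
  for (seed in 4:6) {
    tbl <- randomDesign(9, seed, stimEffect = 0.7, visitEffect = 0.4)
    fit <- rmAnova2x2(tbl)
    face <- tapply(tbl$value[tbl$stimulus == "face"],
                   tbl$subject[tbl$stimulus == "face"], mean)
    house <- tapply(tbl$value[tbl$stimulus == "house"],
                    tbl$subject[tbl$stimulus == "house"], mean)
    tt <- pairedTTest(face, house)
    expect_equal(fit$F[fit$effect == "stimulus"], tt$t^2, tolerance = 1e-10)
    v1 <- tapply(tbl$value[tbl$visit == 1], tbl$subject[tbl$visit == 1], mean)
    v2 <- tapply(tbl$value[tbl$visit == 2], tbl$subject[tbl$visit == 2], mean)
    tt2 <- pairedTTest(v1, v2)
    expect_equal(fit$F[fit$effect == "visit"], tt2$t^2, tolerance = 1e-10)
  }
})

test_that("zero error variance yields an undefined-F signal, not a crash", {
  tbl <- expand.grid(subject = 1:5, stimulus = c("face", "house"),
                     visit = 1:2, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  subj <- c(0, 1, 5, -2, 3)
  tbl$value <- subj[tbl$subject] + 3 * (tbl$stimulus == "face")
  fit <- rmAnova2x2(tbl)
  expect_true(is.na(fit$F[fit$effect == "stimulus"]))
  expect_equal(fit$petaSq[fit$effect == "stimulus"], 1)
  expect_error(rmAnova2x2(tbl[tbl$subject == 1, ]), "at least 2")
})

test_that("partial eta squared stays in [0,1] and grows with F", {
  for (seed in 10:14) {
    fit <- rmAnova2x2(randomDesign(8, seed, stimEffect = runif(1, 0, 3)))
    expect_true(all(fit$petaSq >= 0 & fit$petaSq <= 1, na.rm = TRUE))
  }
  # monotone in F at fixed df: peta = F/(F + df2)
  f <- c(0.5, 1, 4, 30)
  expect_true(all(diff(f / (f + 7)) > 0))
})

test_that("the paired t-test matches hand computation and flips under swap", {
  # differences (1, 2, 3): mean 2, sd 1 -> t = 2 * sqrt(3), df = 2
  x <- c(2, 4, 6)
  y <- c(1, 2, 3)
  tt <- pairedTTest(x, y)
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 2L)
  expect_equal(tt$d, 2)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)

  swapped <- pairedTTest(y, x)
  expect_equal(swapped$t, -tt$t)
  expect_equal(swapped$d, -tt$d)

  same <- pairedTTest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  # constant non-zero difference: undefined t
  und <- pairedTTest(x, x - 2)
  expect_true(is.na(und$t))
})

test_that("Brown-Forsythe matches the median-centred oracle and car", {
  v <- c(1, 2, 3, 10, 20, 30)
  g <- rep(c("a", "b"), each = 3)
  bf <- brownForsythe(v, g)
  # brute force on |x - group median|
  z <- abs(v - rep(c(2, 20), each = 3))
  zg <- tapply(z, g, mean)
  ssB <- sum(3 * (zg - mean(z))^2)
  ssW <- sum((z - rep(zg, each = 3))^2)
  expect_equal(bf$F, (ssB / 1) / (ssW / 4), tolerance = 1e-12)
  expect_equal(bf$df1, 1L)
  expect_equal(bf$df2, 4L)

  skip_if_not_installed("car")
  lv <- car::leveneTest(v ~ factor(g), center = median)
  expect_equal(bf$F, lv[1, "F value"], tolerance = 1e-12)
  expect_equal(bf$p, lv[1, "Pr(>F)"], tolerance = 1e-12)
})

test_that("Brown-Forsythe is location-invariant and zero for identical groups", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(brownForsythe(v, g)$F, 0)
  set.seed(8)
  x <- rnorm(20)
  y <- rnorm(20, sd = 3)
  f1 <- brownForsythe(c(x, y), rep(1:2, each = 20))$F
  f2 <- brownForsythe(c(x, y + 100), rep(1:2, each = 20))$F
  expect_equal(f1, f2, tolerance = 1e-10)
  # zero-spread groups are legitimate input
  expect_silent(brownForsythe(c(1, 1, 1, 2, 3, 4), rep(c("a", "b"), each = 3)))
})

test_that("subject-level effect recovery: both main effects detected, interaction near alpha", {
  # score-level simulation at the generator's default effect sizes:
  # N290-like pattern with stimulus and visit main effects, no interaction
  eff <- defaultEffectSpec()
  eff <- eff[eff$component == "N290", ]
  nRep <- 60
  n <- 80
  hitsStim <- hitsVisit <- hitsInter <- 0
  set.seed(2024)
  for (r in seq_len(nRep)) {
    d <- drawDifferences(eff, n)           # subject true differences
    dev1 <- (d$trueDiff[d$visit == 1] - eff$diffMean[eff$visit == 1]) / 2
    dev2 <- (d$trueDiff[d$visit == 2] - eff$diffMean[eff$visit == 2]) / 2
    noise <- function() rnorm(n, sd = 1)   # measurement noise on cell means
    tbl <- data.frame(
      subject = rep(seq_len(n), 4),
      stimulus = rep(c("face", "house"), each = n, times = 2),
      visit = rep(1:2, each = 2 * n),
      value = c(4.96 + dev1 + noise(), 14.25 - dev1 + noise(),
                9.66 + dev2 + noise(), 18.95 - dev2 + noise()))
    fit <- rmAnova2x2(tbl)
    hitsStim <- hitsStim + (fit$p[fit$effect == "stimulus"] < 0.05)
    hitsVisit <- hitsVisit + (fit$p[fit$effect == "visit"] < 0.05)
    hitsInter <- hitsInter + (fit$p[fit$effect == "interaction"] < 0.05)
  }
  expect_gt(hitsStim / nRep, 0.9)
  expect_gt(hitsVisit / nRep, 0.9)
  expect_lt(hitsInter / nRep, 0.2)         # null effect stays near alpha
})
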