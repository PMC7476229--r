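makeRaw512 <- function(data, events, channels = rownames(data)) {
  new("RawRecording", subject = "p01", visit = 1L, sampleRate = 512,
      channels = channels, data = data, events = events)
}

simpleEvents <- function(onsets, condition = "face") {
  data.frame(onset = as.integer(onsets), condition = condition,
             block = 1L, lookaway = FALSE)
}

test_that("epoching spans -200 to 1000 ms and baseline-corrects exactly", {
  dat <- matrix(5, 2, 2000, dimnames = list(c("Cz", "Oz"), NULL))
  ep <- segmentEpochs(makeRaw512(dat, simpleEvents(300)))
  expect_equal(range(epochTimes(ep)), c(-102, 512) / 512 * 1000)
  expect_equal(max(abs(ep@data)), 0)        # constant trace -> all zero

  # 2 uV before onset, 7 uV after -> post-stimulus samples at 5 uV
  dat2 <- matrix(2, 1, 2000, dimnames = list("Cz", NULL))
  dat2[1, 501:2000] <- 7
  ep2 <- segmentEpochs(makeRaw512(dat2, simpleEvents(500)))
  post <- ep2@data[1, epochTimes(ep2) > 0, 1]
  pre <- ep2@data[1, epochTimes(ep2) < 0, 1]
  expect_equal(unique(post), 5)
  expect_equal(unique(pre), 0)
  # baseline residual is numerically zero
  bIdx <- which(epochTimes(ep2) >= -150 & epochTimes(ep2) <= 0)
  expect_lt(abs(mean(ep2@data[1, bIdx, 1])), 1e-9)
})

test_that("96 events yield 96 epochs, 48 per condition; out-of-bounds events are skipped", {
  cfg <- cohortConfig(nSubjects = 1, sampleRate = 512, noiseSd = 0,
                      artifactRate = 0, lookawayRate = 0, seed = 17)
  rec <- simulateRecording(cfg, buildTemplates(cfg), seed = 18)
  ep <- segmentEpochs(rec)
  expect_equal(dim(ep@data)[3], 96)
  expect_equal(as.integer(table(ep@condition)), c(48L, 48L))

  dat <- matrix(0, 1, 700, dimnames = list("Cz", NULL))
  expect_message(
    ep2 <- segmentEpochs(makeRaw512(dat, simpleEvents(c(50, 150)))),
    "skipped")
  expect_equal(dim(ep2@data)[3], 1)
  expect_equal(ep2@log$skipped, 1L)
})

test_that("the three artifact criteria flag exactly as defined", {
  ch <- c("A", "B", "C", "D")
  ep <- makeEpochs(ch, "face")
  times <- epochTimes(ep)
  noise <- sin(2 * pi * 7 * times / 1000) * 5       # keeps channels non-flat
  for (e in 1:4) ep@data[e, , 1] <- noise
  iAmp <- which.min(abs(times - 300))
  ep@data[1, iAmp, 1] <- 250                        # amplitude criterion
  ep@data[2, , 1] <- 0                              # flatline criterion
  iStep <- which.min(abs(times - 400))
  ep@data[3, iStep:length(times), 1] <-
    ep@data[3, iStep:length(times), 1] + 60         # gradient criterion
  out <- flagArtifacts(ep)
  expect_identical(unname(artifactFlags(out)[, 1]),
                   c("amplitude", "flatline", "gradient", ""))
})

test_that("a 50 uV 10 Hz sinusoid passes all three criteria", {
  ep <- makeEpochs("A", "face")
  ep@data[1, , 1] <- 50 * sin(2 * pi * 10 * epochTimes(ep) / 1000)
  out <- flagArtifacts(ep)
  expect_identical(unname(artifactFlags(out)[, 1]), "")
})

test_that("boundary values do not trigger the strict criteria", {
  ep <- makeEpochs("A", "face")
  times <- epochTimes(ep)
  # exactly +/-200 uV peak, 3 uV range wiggle, 50 uV jumps: all pass
  # triangle wave rising/falling by exactly 50 uV per sample between
  # exactly +200 and -200 uV: every criterion sits on its boundary
  tri <- c(seq(0, 200, by = 50), seq(150, -200, by = -50),
           seq(-150, -50, by = 50))
  ep@data[1, , 1] <- rep(tri, length.out = length(times))
  out <- flagArtifacts(ep)
  expect_identical(unname(artifactFlags(out)[, 1]), "")
})

test_that("artifacts outside the 0-600 ms scan region are never flagged", {
  ep <- makeEpochs("A", "face")
  times <- epochTimes(ep)
  ep@data[1, , 1] <- rep(c(0, 4), length.out = length(times))
  ep@data[1, which.min(abs(times - 800)), 1] <- 300   # beyond 600 ms
  out <- flagArtifacts(ep)
  expect_identical(unname(artifactFlags(out)[, 1]), "")
})

test_that("look-away trials are excluded whole", {
  ep <- makeEpochs("A", c("face", "face"), lookaway = c(TRUE, FALSE))
  ep@data[1, , ] <- rnorm(2 * length(epochTimes(ep)))
  out <- flagArtifacts(ep)
  expect_identical(trialStatus(out),
                   c("excluded:lookaway", "included"))
})

test_that("the 16 percent trial rule and 5-trial electrode rule apply in order", {
  ch <- biosemi32Montage()
  ep <- makeEpochs(ch, rep(c("face", "house"), 5))
  ep@flags[1:6, 1] <- "amplitude"    # 6/32 = 18.75% > 16% -> trial removed
  ep@flags[1:5, 2] <- "amplitude"    # 5/32 = 15.6%  <= 16% -> trial kept
  out <- applyRejection(ep)
  expect_identical(trialStatus(out)[1:2],
                   c("excluded:artifact-fraction", "included"))

  # electrode artifact-free on only 4 surviving trials -> rejected
  ep2 <- makeEpochs(ch, rep("face", 6))
  ep2@flags[1, 1:2] <- "gradient"    # Fp1 free on 4 of 6
  out2 <- applyRejection(ep2)
  expect_identical(rejectedElectrodes(out2)[1], "insufficient-free-trials")
  expect_true(all(rejectedElectrodes(out2)[-1] == ""))

  # exactly 5 free trials survives
  ep3 <- makeEpochs(ch, rep("face", 6))
  ep3@flags[1, 1] <- "gradient"
  expect_identical(rejectedElectrodes(applyRejection(ep3))[1], "")
})

test_that("trial removal precedes electrode rejection", {
  ch <- biosemi32Montage()
  # electrode Fp1 is flagged only in trials that the 16% rule removes, so
  # it keeps 5 free trials among the survivors and is retained
  ep <- makeEpochs(ch, rep("face", 7))
  ep@flags[1:6, 1:2] <- "amplitude"       # both trials removed whole
  out <- applyRejection(ep)
  expect_identical(sum(trialStatus(out) == "included"), 5L)
  expect_identical(rejectedElectrodes(out)[1], "")
})

test_that("the common-average reference subtracts the per-sample mean of usable electrodes", {
  ep <- makeEpochs(c("A", "B"), "face")
  ep@data[1, , 1] <- 4
  ep@data[2, , 1] <- -2
  out <- applyAverageReference(ep)
  expect_equal(unique(out@data[1, , 1]), 3)
  expect_equal(unique(out@data[2, , 1]), -3)
  expect_lt(max(abs(colMeans(out@data[, , 1]))), 1e-9)

  # a flagged electrode does not enter the reference mean
  ep2 <- makeEpochs(c("A", "B", "C"), "face")
  ep2@data[1, , 1] <- 4
  ep2@data[2, , 1] <- -2
  ep2@data[3, , 1] <- 1000            # spiked channel
  ep2@flags[3, 1] <- "amplitude"
  out2 <- applyAverageReference(ep2)
  expect_equal(unique(out2@data[1, , 1]), 3)   # unaffected by C
  expect_equal(unique(out2@data[2, , 1]), -3)

  # fewer than 2 usable electrodes excludes the trial
  ep3 <- makeEpochs(c("A", "B"), "face")
  ep3@flags[1, 1] <- "amplitude"
  out3 <- applyAverageReference(ep3)
  expect_identical(trialStatus(out3), "excluded:reference")
})

test_that("condition averages and the 10-trial inclusion rule behave at the boundary", {
  ch <- biosemi32Montage()
  ep <- makeEpochs(ch, rep(c("face", "house"), each = 12))
  for (tr in 1:24) ep@data[, , tr] <- tr  # distinct constants
  # two face trials with 1 and 3 uV at an electrode -> average 2 uV
  epA <- makeEpochs(ch, c("face", "face"))
  epA@data[, , 1] <- 1
  epA@data[, , 2] <- 3
  erpA <- averageByCondition(epA, minTrials = 1)
  expect_equal(unique(erpA@waveforms$face[1, ]), 2)

  # 9 artifact-free face trials at Oz -> P1 and N290/P400 excluded, Nc kept
  oz <- match("Oz", ch)
  ep@flags[oz, 1:3] <- "gradient"      # 12 - 3 = 9 free face trials
  erp <- averageByCondition(ep, minTrials = 10)
  inc <- componentInclusion(erp)
  expect_false(inc[["P1"]])
  expect_false(inc[["N290P400"]])
  expect_true(inc[["Nc"]])
  expect_equal(unname(includedTrialCounts(erp)[oz, "face"]), 9L)

  # exactly 10 everywhere -> included ("at least 10")
  ep2 <- makeEpochs(ch, rep(c("face", "house"), each = 10))
  inc2 <- componentInclusion(averageByCondition(ep2, minTrials = 10))
  expect_true(all(inc2))
})

test_that("exclusions conserve trials and carry exactly one reason each", {
  cfg <- cohortConfig(nSubjects = 1, sampleRate = 512, artifactRate = 0.3,
                      lookawayRate = 0.3, seed = 19)
  rec <- simulateRecording(cfg, buildTemplates(cfg), seed = 20)
  ep <- applyAverageReference(applyRejection(flagArtifacts(
    segmentEpochs(filterAndDownsample(rec)))))
  st <- trialStatus(ep)
  expect_equal(length(st), 96)
  expect_true(all(st %in% c("included", "excluded:lookaway",
                            "excluded:artifact-fraction",
                            "excluded:reference")))
  expect_equal(sum(st == "included") + sum(st != "included"), 96)
  # flags carry a single reason code
  expect_true(all(artifactFlags(ep) %in%
                    c("", "amplitude", "flatline", "gradient")))
})

test_that("with no injected artifacts or look-aways nothing is rejected", {
  cfg <- cohortConfig(nSubjects = 1, sampleRate = 512, artifactRate = 0,
                      lookawayRate = 0, seed = 23)
  rec <- simulateRecording(cfg, buildTemplates(cfg), seed = 24)
  ep <- applyRejection(flagArtifacts(segmentEpochs(filterAndDownsample(rec))))
  expect_true(all(trialStatus(ep) == "included"))
  expect_true(all(artifactFlags(ep) == ""))
  expect_true(all(rejectedElectrodes(ep) == ""))
})

test_that("the full chain matches the hand-computed 3-electrode fixture", {
  ep <- handFixtureEpochs()
  out <- applyAverageReference(applyRejection(flagArtifacts(ep),
                                              maxBadFraction = 0.34,
                                              minFreeTrials = 2))
  expect_identical(unname(artifactFlags(out)[, 1]), c("", "", "amplitude"))
  expect_identical(unname(artifactFlags(out)[, 3]), c("", "gradient", ""))
  expect_identical(trialStatus(out),
                   c("included", "included", "included", "excluded:lookaway"))
  expect_true(all(rejectedElectrodes(out) == ""))

  erp <- averageByCondition(out, minTrials = 1)
  k <- -102:512
  post <- which(k == 50)     # an arbitrary post-stimulus sample
  pre <- which(k == -50)
  # hand computation: after referencing, trial values per electrode are
  #   t1 (face): E1  2, E2 -2   (E3 flagged)
  #   t2 (face): E1  4, E2 -2, E3 -2
  #   t3 (house): E1 2, E3 -2   (E2 flagged)
  expect_equal(unname(erp@waveforms$face["E1", post]), 3)
  expect_equal(unname(erp@waveforms$face["E2", post]), -2)
  expect_equal(unname(erp@waveforms$face["E3", post]), -2)
  expect_equal(unname(erp@waveforms$house["E1", post]), 2)
  expect_equal(unname(erp@waveforms$house["E3", post]), -2)
  expect_true(is.na(erp@waveforms$house["E2", post]))
  expect_equal(unname(erp@waveforms$face["E1", pre]), 0)
  expect_equal(unname(includedTrialCounts(erp)),
               matrix(c(2L, 2L, 1L, 1L, 0L, 1L), 3, 2))
})
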