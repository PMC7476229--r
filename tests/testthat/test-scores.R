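p1set <- c("PO3", "O1", "Oz", "O2", "PO4")

test_that("mean amplitude averages over window samples then electrodes", {
  erp <- makeERP(face = 5)
  expect_equal(meanAmplitude(erp, "P1", "face"), 5)

  # two critical electrodes at 3 and 7 uV, the rest of the montage wild
  wf <- matrix(rnorm(32 * 615, sd = 40), 32, 615,
               dimnames = list(biosemi32Montage(), NULL))
  wf[p1set, ] <- 3
  wf[c("Oz", "O2"), ] <- 7
  wf[c("PO3", "O1", "PO4"), ] <- 3
  erp2 <- makeERP(face = wf)
  expect_equal(meanAmplitude(erp2, "P1", "face"), (3 * 3 + 2 * 7) / 5)

  # linear ramp 0..10 uV spanning exactly 90-180 ms on one of five
  # electrodes, others zero -> about 1.0 (grid-sampling error allowed)
  wf3 <- matrix(0, 32, 615, dimnames = list(biosemi32Montage(), NULL))
  times <- analysisTimes(512)
  idx <- which(times >= 90 & times <= 180)
  wf3["Oz", idx] <- 10 * (times[idx] - 90) / 90
  erp3 <- makeERP(face = wf3)
  expect_equal(meanAmplitude(erp3, "P1", "face"), 1.0, tolerance = 0.05)
})

test_that("mean amplitude is NA when a critical electrode is rejected", {
  wf <- matrix(2, 32, 615, dimnames = list(biosemi32Montage(), NULL))
  wf["Oz", ] <- NA_real_
  erp <- makeERP(face = wf)
  expect_true(is.na(meanAmplitude(erp, "P1", "face")))
  expect_equal(meanAmplitude(erp, "Nc", "face"), 2)  # Nc set unaffected
})

test_that("peak latency finds the extreme sample, averages electrodes, and breaks ties early", {
  times <- analysisTimes(512)
  wf <- matrix(0, 32, 615, dimnames = list(biosemi32Montage(), NULL))
  g <- exp(-(times - 135)^2 / (2 * 20^2))
  wf[p1set, ] <- matrix(g, 5, 615, byrow = TRUE)
  erp <- makeERP(face = wf)
  expect_equal(peakLatency(erp, "P1", "face"), 135, tolerance = 2 / 135)

  # peaks at two grid times on two electrodes average
  idx <- which(times >= 90 & times <= 180)
  tA <- times[idx][10]
  tB <- times[idx][30]
  wf2 <- matrix(0, 32, 615, dimnames = list(biosemi32Montage(), NULL))
  wf2["Oz", times == tA] <- 1
  wf2[c("PO3", "O1", "O2", "PO4"), times == tB] <- 1
  erp2 <- makeERP(face = wf2)
  expect_equal(as.numeric(peakLatency(erp2, "P1", "face")),
               (tA + 4 * tB) / 5)

  # flat window: window start returned, flagged low-confidence
  erp3 <- makeERP(face = 1)
  lat <- peakLatency(erp3, "P1", "face")
  expect_equal(as.numeric(lat), times[idx][1])
  expect_true(attr(lat, "lowConfidence"))
})

test_that("negative components use the minimum and unsupported latencies error", {
  times <- analysisTimes(512)
  wf <- matrix(0, 32, 615, dimnames = list(biosemi32Montage(), NULL))
  n290set <- c("P3", "PO3", "O1", "Oz", "O2", "PO4", "P4")
  g <- -exp(-(times - 240)^2 / (2 * 25^2))
  wf[n290set, ] <- matrix(g, 7, 615, byrow = TRUE)
  erp <- makeERP(face = wf, house = wf)
  expect_equal(as.numeric(peakLatency(erp, "N290", "face")), 240,
               tolerance = 2 / 240)
  expect_error(peakLatency(erp, "N290", "house"),
               class = "infantERP_unsupportedMeasure")
  expect_error(peakLatency(erp, "P400", "face"),
               class = "infantERP_unsupportedMeasure")
})

test_that("peak-to-trough subtracts the preceding component as specified", {
  times <- analysisTimes(512)
  # houses: P1 mean 10.5, N80 mean -3.53 -> corrected 14.03
  wf <- matrix(0, 32, 615, dimnames = list(biosemi32Montage(), NULL))
  wf[p1set, times <= 90] <- -3.53
  wf[p1set, times > 90] <- 10.5
  erp <- makeERP(house = wf)
  expect_equal(peakToTrough(erp, "P1", "house"), 14.03)

  # zero preceding peak: corrected equals the raw mean
  wf0 <- matrix(0, 32, 615, dimnames = list(biosemi32Montage(), NULL))
  wf0[p1set, times >= 90 & times <= 180] <- 6
  erp0 <- makeERP(face = wf0)
  expect_equal(peakToTrough(erp0, "N290", "face"),
               meanAmplitude(erp0, "N290", "face") - 6 * 5 / 7)

  # two-bump waveform with known values: N290 window constant -4, P1-window
  # spike of 6 on every N290 electrode -> -4 - 6 = -10
  n290set <- c("P3", "PO3", "O1", "Oz", "O2", "PO4", "P4")
  wf2 <- matrix(0, 32, 615, dimnames = list(biosemi32Montage(), NULL))
  wf2[n290set, times >= 170 & times <= 300] <- -4
  spikeCol <- which(times >= 90 & times <= 180)[5]
  wf2[n290set, spikeCol] <- 6
  erp2 <- makeERP(face = wf2)
  expect_equal(peakToTrough(erp2, "N290", "face"), -10)

  # P400 subtracts the most negative N290-window sample
  wf3 <- matrix(0, 32, 615, dimnames = list(biosemi32Montage(), NULL))
  wf3[n290set, times >= 300 & times <= 500] <- 8
  trough <- which(times >= 170 & times <= 300)[10]
  wf3[n290set, trough] <- -5
  erp3 <- makeERP(face = wf3)
  expect_equal(peakToTrough(erp3, "P400", "face"), 8 - (-5))

  expect_error(peakToTrough(erp3, "Nc", "face"), "P1, N290 and P400")
})

test_that("difference scores are exact subtractions and antisymmetric", {
  expect_equal(differenceScore(7.31, 16.6), -9.29)
  expect_equal(differenceScore(5, 5), 0)
  expect_equal(differenceScore(10.2, 3.1), 7.1)
  expect_equal(differenceScore(3.1, 10.2), -differenceScore(10.2, 3.1))
})

test_that("scores are linear in the waveform and latency is shift-invariant", {
  set.seed(12)
  times <- analysisTimes(512)
  wf <- matrix(rnorm(32 * 615), 32, 615,
               dimnames = list(biosemi32Montage(), NULL))
  erp <- makeERP(face = wf)
  erpScaled <- makeERP(face = 3 * wf)
  erpShifted <- makeERP(face = wf + 2)
  for (comp in c("P1", "N290", "Nc")) {
    expect_equal(meanAmplitude(erpScaled, comp, "face"),
                 3 * meanAmplitude(erp, comp, "face"))
    expect_equal(meanAmplitude(erpShifted, comp, "face"),
                 meanAmplitude(erp, comp, "face") + 2)
  }
  expect_equal(peakToTrough(erpScaled, "N290", "face"),
               3 * peakToTrough(erp, "N290", "face"))
  expect_equal(as.numeric(peakLatency(erpShifted, "P1", "face")),
               as.numeric(peakLatency(erp, "P1", "face")))
})

test_that("the tidy scores table and difference table are consistent", {
  erp1 <- makeERP(face = 4, house = 1)
  erp2 <- makeERP(face = -2, house = 3)
  erp2@visit <- 2L
  sc <- scoreComponents(list(erp1, erp2))
  expect_named(sc, c("subject", "visit", "component", "condition",
                     "measure", "value"))
  ma <- sc[sc$measure == "mean_amplitude", ]
  expect_equal(unique(ma$value[ma$condition == "face" & ma$visit == 1]), 4)
  d <- differenceScores(sc)
  expect_equal(unique(d$value[d$visit == 1]), 3)
  expect_equal(unique(d$value[d$visit == 2]), -5)
  # excluded families propagate NA
  erp3 <- makeERP(face = 4, house = 1,
                  inclusion = c(P1 = FALSE, N290P400 = TRUE, Nc = TRUE))
  sc3 <- scoreComponents(list(erp3))
  expect_true(all(is.na(sc3$value[sc3$component == "P1"])))
  expect_false(anyNA(sc3$value[sc3$component == "Nc"]))
})
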