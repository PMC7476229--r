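# Shared fixtures: all built in code at test time.

# Small fast cohort configuration (512 Hz, short task).
smallConfig <- function(nSubjects = 2, ...) {
  cohortConfig(nSubjects = nSubjects, nTrialsPerCondition = 12,
               nBlocks = 2, sampleRate = 512, seed = 101, ...)
}

# Empty epoch container on the standard 512 Hz grid.
makeEpochs <- function(channels, conditions, lookaway = NULL,
                       subject = "t01", visit = 1L) {
  times <- analysisTimes(512)
  n <- length(conditions)
  if (is.null(lookaway)) lookaway <- rep(FALSE, n)
  new("EpochSet", subject = subject, visit = as.integer(visit),
      times = times, channels = channels,
      data = array(0, c(length(channels), length(times), n),
                   dimnames = list(channels, NULL, NULL)),
      condition = conditions, block = rep(1L, n), lookaway = lookaway,
      flags = matrix("", length(channels), n),
      trialStatus = rep("included", n),
      rejectedChannels = rep("", length(channels)),
      referenced = FALSE, log = list(presented = n, skipped = 0L))
}

# Subject ERP with waveforms supplied as channel x time matrices (recycled
# constants allowed).  Missing condition defaults to zeros.
makeERP <- function(face = 0, house = 0, channels = biosemi32Montage(),
                    nTrials = 30L, inclusion = NULL) {
  times <- analysisTimes(512)
  expand <- function(x) {
    if (is.matrix(x)) return(x)
    matrix(x, length(channels), length(times),
           dimnames = list(channels, NULL))
  }
  wf <- list(face = expand(face), house = expand(house))
  rownames(wf$face) <- rownames(wf$house) <- channels
  if (is.null(inclusion))
    inclusion <- c(P1 = TRUE, N290P400 = TRUE, Nc = TRUE)
  new("SubjectERP", subject = "t01", visit = 1L, times = times,
      channels = channels, waveforms = wf,
      nTrials = matrix(nTrials, length(channels), 2,
                       dimnames = list(channels, c("face", "house"))),
      inclusion = inclusion, usable = TRUE)
}

# The hand-computed 3-electrode, 4-trial preprocessing fixture.
#
# Sample index k runs -102..512 (t = k/512*1000 ms).  Post-stimulus
# samples (k >= 1) carry value + alternation (+2 at odd k, -2 at even k,
# common to all electrodes); pre-stimulus samples carry the baseline
# constant.  Trial composition:
#   trial 1 (face):  base (2,0,5),  values (5, 1, 0), 250 uV spike on E3
#                    at k = 150  -> E3 flagged "amplitude"
#   trial 2 (face):  base (1,1,1),  values (4,-2,-2), clean
#   trial 3 (house): base (0,0,0),  values (6, 1, 2), +60 uV step on E2
#                    from k = 100 -> E2 flagged "gradient"
#   trial 4 (house): look-away, excluded whole
handFixtureEpochs <- function() {
  ch <- c("E1", "E2", "E3")
  ep <- makeEpochs(ch, c("face", "face", "house", "house"),
                   lookaway = c(FALSE, FALSE, FALSE, TRUE))
  k <- -102:512
  alt <- ifelse(k >= 1, ifelse(k %% 2 == 1, 2, -2), 0)
  post <- as.numeric(k >= 1)
  fill <- function(base, vals) {
    # raw = base + (k>=1)*(value + alt)
    m <- matrix(0, 3, length(k))
    for (e in 1:3) m[e, ] <- base[e] + post * (vals[e] + alt)
    m
  }
  ep@data[, , 1] <- fill(c(2, 0, 5), c(5, 1, 0))
  ep@data[3, which(k == 150), 1] <- 5 + 250   # raw spike (250 post-baseline)
  ep@data[, , 2] <- fill(c(1, 1, 1), c(4, -2, -2))
  ep@data[, , 3] <- fill(c(0, 0, 0), c(6, 1, 2))
  step <- k >= 100
  ep@data[2, step, 3] <- ep@data[2, step, 3] + 60
  ep@data[, , 4] <- fill(c(0, 0, 0), c(9, 9, 9))
  # baseline correction as segmentEpochs would do it
  bIdx <- which(ep@times >= -150 & ep@times <= 0)
  for (tr in 1:4) {
    base <- rowMeans(ep@data[, bIdx, tr])
    ep@data[, , tr] <- ep@data[, , tr] - base
  }
  ep
}
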