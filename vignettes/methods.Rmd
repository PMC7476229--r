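---
title: "Methods: simulating and analysing longitudinal infant face-categorization ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing longitudinal infant face-categorization ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantERP)
```

## The scientific problem

Infants discriminate human faces from other visual categories within the
first months of life, and this discrimination is visible in event-related
potentials (ERPs): the average EEG voltage time-locked to stimulus onset.
Four components are commonly scored in infant face studies, each on its
own electrode set and time window:

| component | window (ms) | electrodes | polarity | interpretation |
|-----------|-------------|------------|----------|----------------|
| P1   | 90–180  | PO3, O1, Oz, O2, PO4 | positive | low-level visual processing |
| N290 | 170–300 | P3, PO3, O1, Oz, O2, PO4, P4 | negative | face encoding (N170 precursor) |
| P400 | 300–500 | P3, PO3, O1, Oz, O2, PO4, P4 | positive | face processing / N290 carry-over |
| Nc   | 300–600 | Fz, C3, C4 | negative | attention allocation |

(The small N80 trough at 70–90 ms on the P1 electrodes is scored only as
the reference for the P1 peak-to-trough correction.)

The quantity of interest per subject, visit and component is the
**face–house difference score** — mean amplitude to faces minus mean
amplitude to houses.  At the cohort level the package asks two questions:
do the components discriminate faces from houses at each visit (2×2
within-subject ANOVA: stimulus × visit), and how do individual infants'
discrimination *states* move between visits (descriptive Markov transition
tables over the three states negative / none / positive, classified at a
±1.5 µV threshold)?

Because longitudinal infant EEG is not publicly shareable, the package is
organised around a synthetic-cohort generator with full ground truth, so
every downstream stage is testable end to end without any data download.

## The synthetic cohort

`cohortConfig()` fixes the study conditions: 80 infants seen at two
visits; 48 face and 48 house trials per visit, presented in 4 blocks of 24
with every stimulus identity appearing once per block in randomized
order; 1000 ms trials separated by a 700–1000 ms uniformly jittered
inter-stimulus interval; a 32-channel 10–20 montage sampled at 2048 Hz
(512 Hz can be emitted directly when the downsampling stage itself is not
under study — all cohort-scale runs in the package's tests and in
`scripts/acceptance.R` use 512 Hz for speed; single-recording tests
exercise the 2048 → 512 Hz path).

**Templates.** Each component is a Gaussian bump in time — centre and
width chosen at the canonical infant latencies (P1 at 135 ms, N290 at
235 ms, P400 at 400 ms, Nc at 450 ms) — constant across its electrode
set.  Because neighbouring bumps leak into each other's windows, the five
bump amplitudes per condition/visit are obtained by solving the 5×5
linear system mapping amplitudes to windowed means, so the rendered
noise-free signal has *exactly* the requested windowed mean on each
component's electrode set (to < 0.01 µV).  Each template additionally
carries a uniform opposite-sign offset on the electrodes outside its set,
making the montage average zero at every sample.  This design choice
matters: the preprocessing chain re-references to the common average, and
a template confined strictly to its own electrodes would have its
windowed mean shifted by roughly 1 µV by that reference.  With zero-sum
templates the reference is a no-op on the clean signal and recovery is
exact; `buildTemplates(compensate = FALSE)` restores the confined
behaviour for users who want it.

**Default amplitudes.** The group-level windowed-mean targets
(`defaultGroupMeans()`) follow the published group means of a large
two-visit infant face/house cohort — e.g. P1 faces 7.65 / houses 10.5 µV,
N290 faces 7.31 / houses 16.6 µV — with stimulus and visit effects
combined additively (the emulated study reported no stimulus-by-visit
interactions).  Subject-level variation enters through the difference
score: per component, each subject's true face–house difference at the
two visits is drawn from a bivariate normal (`defaultEffectSpec()`; SDs
7.0 / 6.9 / 8.5 / 5.6 µV for P1 / N290 / P400 / Nc, derived from the
reported three-state subgroup spreads; between-visit correlation 0.5, a
moderate test–retest reliability typical of infant ERP difference
scores).  Half the subject's deviation is added to the face target and
half subtracted from the house target, so the rendered difference equals
the drawn value exactly.

**Noise and contamination.** Per channel, independent noise with total SD
15 µV, 70 % of the variance carried by 1/f ("pink") noise and the rest
white — an EEG-like spectrum without spatial covariance modelling.
Look-aways are Bernoulli per trial at rate 0.35, and artifacts Bernoulli
per trial-electrode at rate 0.02; together these reproduce the ≈30
included trials per condition typical of infant testing at this design
size.  Three artifact kinds are injected with equal probability: a 60 ms
pulse peaking at ±250 µV, a 450 ms flatline, and a 400 µV step.  The
magnitudes are deliberately large because the injected defect must still
violate a rejection criterion *after* the 0.1–30 Hz zero-phase analysis
filter: a literal single-sample spike, for instance, is attenuated to a
few microvolts by a 30 Hz low-pass and would be undetectable by design.

**What the generator does not emulate.** No head-model or dipole
geometry; no spatially correlated noise; no subject-level variation in
overall (non-difference) amplitude; no trial-to-trial latency jitter of
the components; look-away behaviour is an i.i.d. flag rather than coded
gaze.  Consequently, passing recovery tests demonstrate that the
*pipeline arithmetic* is faithful under realistic SNR, not that the
pipeline is robust to every pathology of real infant EEG.  One visible
consequence: with no between-subject variance in overall amplitude, the
simulated visit-effect F statistics are far larger than anything seen in
real data.

## Preprocessing

`preprocessRecording()` implements, in order:

1. **Filter**: zero-phase 0.1 Hz high-pass and 30 Hz low-pass (4th-order
   Butterworth, ≈24 dB/oct one-way; the forward–backward pass squares the
   magnitude response, which we accept in exchange for zero phase —
   latency measures must not be shifted), plus a 50 Hz notch (2nd-order,
   Q = 35).  Filters are realized as cascaded biquad sections applied in
   compiled code: a 0.1 Hz high-pass expressed as a single 4th-order
   transfer function is numerically degenerate at these sampling rates.
   Each channel is demeaned and reflection-padded (3 s, odd symmetry)
   before filtering.
2. **Decimate** to 512 Hz (integer factor; alias-free behind the 30 Hz
   low-pass), rescaling event onsets.
3. **Epoch** from −200 to 1000 ms around each onset on the 512 Hz grid
   (102 samples before, 512 after; the first sample therefore sits at
   −199.2 ms, the closest grid point to −200), **baseline-correcting**
   by the −150–0 ms mean per electrode per trial.
4. **Exclude look-away trials whole**, then **flag artifacts** per
   trial-electrode within 0–600 ms post-stimulus: amplitude beyond
   ±200 µV, any 200 ms window with peak-to-peak range below 3 µV, or a
   consecutive-sample change above 50 µV.  All inequalities are strict,
   so a value of exactly ±200 µV, a range of exactly 3 µV and a jump of
   exactly 50 µV all pass.  Window endpoints are closed throughout the
   package: a sample belongs to a window when start ≤ t ≤ end.
5. **Reject**: first remove whole trials whose flagged electrodes exceed
   16 % of the full montage (strict: with 32 channels, ≥6 flagged
   electrodes), then reject electrodes with fewer than 5 artifact-free
   surviving trials, pooled over conditions.  Trial removal runs first so
   that one globally bad trial cannot doom electrodes; the original
   order and denominator are not documented for the emulated protocol,
   so both choices are explicit package decisions.
6. **Common-average reference** per trial over that trial's unflagged,
   non-rejected electrodes; flagged electrodes neither contribute to nor
   receive the reference.
7. **Average per condition** per electrode over trials where the
   electrode is unflagged.  A subject-visit enters a component family's
   analyses only when every critical electrode retains ≥10 trials in both
   conditions.

A noise-free cohort run recovers the template windowed means to within
0.05 µV after all of the above (the tests pin this down); the residual is
filter pass-band ripple.  On noise-free data the flatline criterion
fires, correctly, everywhere — validation runs therefore disable flagging
(`flagging = FALSE`), which is a stage toggle, not a special case in the
algorithms.

## Component scoring

`meanAmplitude()` is the arithmetic mean over window samples then over
critical electrodes.  `peakLatency()` takes, per electrode, the time of
the extreme sample (maximum for positive components, minimum for
negative) and averages across electrodes; ties break to the earliest
sample, an all-flat window returns the window start flagged
low-confidence, and latency is refused (classed error) for combinations
without a reliable peak — only P1 (both conditions) and N290 (faces) are
supported.  Latencies live on the 512 Hz grid (≈1.95 ms); no sub-sample
interpolation.

`peakToTrough()` corrects each of P1, N290, P400 for carry-over from the
preceding deflection: P1 minus the N80 *windowed mean* (70–90 ms — the
preceding trough is defined as a mean, not an extreme), N290 minus the
most positive P1-window sample, P400 minus the most negative N290-window
sample.  The preceding peak is evaluated on the *current* component's
electrode set (default), so the subtraction involves matched electrodes;
`precedingOn = "preceding"` switches to the preceding component's own
set.  Note one asymmetry this resolves: P1 uses five electrodes but N290
seven, so the two conventions genuinely differ.

Peak picking on single-subject averages is noise-biased: the extreme of
signal + residual noise drifts toward window edges, and at ≈30 trials per
condition we observe a +4–8 ms bias in per-subject mean latencies.  The
grand-average waveform does not suffer from this, which is why the
acceptance script reports grand-average latencies.

## Trajectories

`classifyState()` maps a difference score to negative / none / positive
with the *inclusive* boundary |value| ≤ threshold → none (the threshold
defaults to 1.5 µV; it is a scientific convention, not a fitted quantity,
and is exposed as a parameter without any default sensitivity sweep).
`buildTransitionTable()` cross-tabulates Visit-1 against Visit-2 states,
row-normalizes to transition probabilities (rows with empty Visit-1
groups are NaN and flagged), and `summarizeDominant()` derives the four
comparison percentages: dominant-group share per visit, persistence
(stayers ÷ Visit-1 dominant size), mover share (non-dominant Visit-1
subjects ending dominant ÷ non-dominant size), and both-visit dominant
share.  Percentages are rounded half-up — 82.5 % prints as 83 % — to
integers, except the both-visit share which keeps two decimals; raw
values are always retained alongside.  Subjects missing a component at
either visit drop out of that component's table only.  The model is
purely descriptive: no likelihood, stationarity assumption, or tests on
the transition probabilities.

## Inferential statistics

`rmAnova2x2()` implements the fully-within 2×2 decomposition from sums
of squares, testing each effect against its own subject-by-effect
stratum: F(1, n−1), two-sided p, and partial eta squared
SS~effect~/(SS~effect~+SS~error~).  With two-level factors sphericity is
trivially satisfied, so no correction is applied.  Cell means enter with
equal weight per subject (condition averages are computed first), and
zero error variance yields an undefined-F signal rather than an error.
The implementation is pinned, in the tests, against `aov()`'s
error-stratum decomposition and against the exact F = t² identity with
the paired t-test.  `pairedTTest()` returns t, df, two-sided p and
Cohen's d = mean(diff)/SD(diff); identical inputs give t = 0 while a
zero-variance non-zero difference is undefined.  `brownForsythe()` is the
one-way ANOVA on absolute deviations from group medians, cross-checked
against `car::leveneTest(center = median)`.

Calibration is part of the acceptance suite: on 2000 null simulations at
n = 80 the stimulus-effect rejection rate at α = 0.05 must stay inside
the binomial 99 % interval, and at the generator's default effect sizes
both main effects are detected with power > 0.9 while the (truly null)
interaction stays near α.

## Numerical and design notes

* All windows are closed intervals on the sampling grid; the −200 ms
  epoch edge maps to −199.2 ms at 512 Hz.
* Event onsets are snapped to the decimation grid at generation time so
  the 2048 → 512 Hz path is sample-exact.
* The 200 ms flatline window is 103 samples at 512 Hz, slid one sample at
  a time, fully inside the 0–600 ms scan region.
* All randomness flows from one integer seed; identical seeds give
  bit-identical recordings and byte-identical output tables.
* Recordings are rendered lazily (a closure per subject-visit) so an
  80-subject cohort never holds 160 traces in memory.
* Electrode rejection pools trials across conditions (the per-condition
  alternative is not what the emulated protocol describes).
* Problem sizes used by the tests: unit tests run on 1–15-subject
  cohorts at 512 Hz; the acceptance checks run one full 80-subject
  cohort, the package's own choice of study-scale validation.

## Known limitations

* The generator's noise, artifact and look-away rates are stated
  assumptions — the emulated study reports none of these — so absolute
  SNR-dependent quantities (e.g. per-subject latency SDs) should not be
  read as predictions of real data.
* Group-level F values from real infant cohorts are not reproducible from
  simulation and are treated only as format references.
* No ocular-artifact correction (ICA/regression), no electrode
  interpolation, and no reference schemes other than the common average
  are provided.
* EDF export is not implemented; the documented TSV layout is the
  interchange format.
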