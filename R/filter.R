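## Zero-phase IIR filtering.  Filters are designed as cascaded biquad
## sections (analog Butterworth prototype + bilinear transform) because a
## 0.1 Hz high-pass expressed as a single 4th-order transfer function is
## numerically degenerate at EEG sampling rates; each section is applied
## forward and backward in compiled code.

## Q factors of the two second-order sections of a 4th-order Butterworth.
butterworth4Q <- function() 1 / (2 * cos(pi * c(1, 3) / 8))

## One second-order section, rows (b0, b1, b2, a0, a1, a2).
biquad <- function(fc, fs, Q, type = c("high", "low")) {
  type <- match.arg(type)
  K <- tan(pi * fc / fs)
  nm <- 1 / (1 + K / Q + K^2)
  a <- c(1, 2 * (K^2 - 1) * nm, (1 - K / Q + K^2) * nm)
  b <- if (type == "high") c(1, -2, 1) * nm else c(K^2, 2 * K^2, K^2) * nm
  c(b, a)
}

## 4th-order Butterworth (~24 dB/oct one-way) as two biquads.
butterSos <- function(fc, fs, type) {
  do.call(rbind, lapply(butterworth4Q(), function(q) biquad(fc, fs, q, type)))
}

## 2nd-order notch at f0 with quality factor Q.
notchSos <- function(f0, fs, Q = 35) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * Q)
  matrix(c(1 / (1 + al), -2 * cos(w0) / (1 + al), 1 / (1 + al),
           1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al)),
         nrow = 1)
}

## Zero-phase application over the columns of a samples x channels matrix,
## with per-column demeaning (the high-pass removes DC anyway) and
## odd-symmetric reflection padding against edge transients.
zeroPhaseFilter <- function(x, sos, fs, padSeconds = 3) {
  n <- nrow(x)
  x <- sweep(x, 2, colMeans(x))
  p <- min(n - 1L, round(padSeconds * fs))
  top <- 2 * matrix(x[1, ], p, ncol(x), byrow = TRUE) - x[(p + 1):2, , drop = FALSE]
  bot <- 2 * matrix(x[n, ], p, ncol(x), byrow = TRUE) - x[(n - 1):(n - p), , drop = FALSE]
  y <- sosFiltFiltCpp(rbind(top, x, bot), sos)
  y[(p + 1):(p + n), , drop = FALSE]
}

#' Filter and downsample a raw recording
#'
#' Applies the analysis filter -- a zero-phase band-pass of 0.1-30 Hz
#' (4th-order Butterworth sections, about 24 dB/oct one-way, magnitude
#' squared by the forward-backward pass) plus a 50 Hz notch (2nd-order,
#' Q = 35) -- and then decimates to the 512 Hz analysis rate, rescaling
#' event onsets.  Decimation after the 30 Hz low-pass is alias-free.
#'
#' @param raw a [RawRecording-class].
#' @param highpass,lowpass,notch corner/centre frequencies in Hz; `NULL`
#'   disables a stage.
#' @param targetRate analysis rate in Hz; the input rate must be an
#'   integer multiple.
#' @return a [RawRecording-class] at `targetRate`.
#' @export
filterAndDownsample <- function(raw, highpass = 0.1, lowpass = 30,
                                notch = 50, targetRate = 512) {
  fs <- raw@sampleRate
  R <- fs / targetRate
  if (R != round(R))
    stop("sample rate ", fs, " is not an integer multiple of ", targetRate)
  sos <- rbind(
    if (!is.null(highpass)) butterSos(highpass, fs, "high"),
    if (!is.null(lowpass)) butterSos(lowpass, fs, "low"),
    if (!is.null(notch)) notchSos(notch, fs))
  x <- t(raw@data)
  if (!is.null(sos)) x <- zeroPhaseFilter(x, sos, fs)
  keep <- seq(1, nrow(x), by = R)
  events <- raw@events
  events$onset <- as.integer((events$onset - 1) / R + 1)
  out <- t(x[keep, , drop = FALSE])
  dimnames(out) <- list(raw@channels, NULL)
  new("RawRecording", subject = raw@subject, visit = raw@visit,
      sampleRate = targetRate, channels = raw@channels,
      data = out, events = events)
}
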