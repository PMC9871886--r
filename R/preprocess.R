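# Preprocessing: zero-phase IIR filtering, window cropping, one-hot
# labels, per-trial min-max scaling. The canonical pipeline order is
# filter -> crop -> scale (applyPipeline enforces it).

#' Filter specification
#'
#' @param kind `"bandpass"`, `"notch"` or `"none"`.
#' @param low,high bandpass edges in Hz (required for `"bandpass"`).
#' @param notchFreq notch center in Hz (required for `"notch"`).
#' @return A list of class `"FilterSpec"`.
#' @export
filterSpec <- function(kind = c("bandpass", "notch", "none"), low = NULL,
                       high = NULL, notchFreq = NULL) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    if (is.null(low) || is.null(high) || low <= 0 || low >= high)
      stop("filterSpec: bandpass needs 0 < low < high")
  }
  if (kind == "notch" && (is.null(notchFreq) || notchFreq <= 0))
    stop("filterSpec: notch needs a positive notchFreq")
  structure(list(kind = kind, low = low, high = high,
                 notchFreq = notchFreq), class = "FilterSpec")
}

filterChannels <- function(epochs, b, a) {
  d <- dim(epochs@samples)
  out <- epochs@samples
  flt <- signal::Arma(b = b, a = a)
  for (i in seq_len(d[1L]))
    for (c in seq_len(d[2L]))
      out[i, c, ] <- signal::filtfilt(flt, epochs@samples[i, c, ])
  epochSet(out, epochs@fs, epochs@labels, epochs@channelNames)
}

#' Zero-phase bandpass filter
#'
#' Forward-backward (zero-phase, no group delay) Butterworth filter of
#' order 4, applied independently to every channel of every trial.
#'
#' @param epochs an [EpochSet-class].
#' @param spec a [filterSpec()] (kind `"bandpass"` or `"none"`), or `NULL`
#'   when `low`/`high` are given directly.
#' @param low,high band edges in Hz (ignored when `spec` is supplied).
#' @param order Butterworth order of the one-pass prototype.
#' @return The filtered [EpochSet-class]; `kind = "none"` returns the
#'   input unchanged.
#' @export
bandpassFilter <- function(epochs, spec = NULL, low = NULL, high = NULL,
                           order = 4L) {
  if (is.null(spec)) spec <- filterSpec("bandpass", low = low, high = high)
  if (spec$kind == "none") return(epochs)
  if (spec$kind == "notch") return(notchFilter(epochs, spec$notchFreq))
  nyq <- epochs@fs / 2
  if (spec$high >= nyq)
    stop("bandpassFilter: band edges must lie below the Nyquist frequency (",
         nyq, " Hz)")
  bt <- signal::butter(order, c(spec$low, spec$high) / nyq, type = "pass")
  filterChannels(epochs, bt$b, bt$a)
}

#' Zero-phase notch filter
#'
#' Second-order IIR notch (constrained biquad) at `freq` with quality
#' factor `q`, run forward-backward. Used to suppress power-line
#' interference (e.g. 50 Hz) while leaving bands more than a few Hz away
#' essentially untouched.
#'
#' @param epochs an [EpochSet-class].
#' @param freq notch center frequency, Hz.
#' @param q quality factor (center / -3 dB bandwidth).
#' @return The filtered [EpochSet-class].
#' @export
notchFilter <- function(epochs, freq, q = 30) {
  nyq <- epochs@fs / 2
  if (freq >= nyq)
    stop("notchFilter: freq must lie below the Nyquist frequency (", nyq,
         " Hz)")
  w0 <- 2 * pi * freq / epochs@fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  filterChannels(epochs, b / a[1L], a / a[1L])
}

#' Crop a time window out of every trial
#'
#' Keeps the half-open interval `[tStart, tEnd)` (0-based sample
#' indexing), i.e. `round((tEnd - tStart) * fs)` samples per trial.
#'
#' @param epochs an [EpochSet-class].
#' @param tStart,tEnd window in seconds relative to trial onset.
#' @return The cropped [EpochSet-class].
#' @export
cropWindow <- function(epochs, tStart, tEnd) {
  fs <- epochs@fs
  nT <- nTimepoints(epochs)
  dur <- nT / fs
  if (tStart < 0 || tStart >= tEnd || tEnd > dur + 1e-9)
    stop("cropWindow: need 0 <= tStart < tEnd <= ", dur, " s")
  n <- round((tEnd - tStart) * fs)
  i0 <- floor(tStart * fs) + 1
  if (i0 + n - 1 > nT)
    stop("cropWindow: window extends past the end of the trial")
  epochSet(epochs@samples[, , i0:(i0 + n - 1), drop = FALSE], fs,
           epochs@labels, epochs@channelNames)
}

#' One-hot encode class labels
#'
#' Class `k` (zero-based) maps to the unit vector with a 1 in position
#' `k + 1`; e.g. four motor-imagery classes become `[1,0,0,0]` ...
#' `[0,0,0,1]`.
#'
#' @param labels zero-based integer class codes.
#' @param nClasses number of classes.
#' @return A `length(labels) x nClasses` 0/1 matrix, each row summing to 1.
#' @export
oneHot <- function(labels, nClasses) {
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= nClasses))
    stop("oneHot: labels must lie in 0..", nClasses - 1L)
  m <- matrix(0, length(labels), nClasses)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

#' Decode one-hot rows back to zero-based labels
#'
#' @param m a one-hot (or softmax probability) matrix.
#' @return Zero-based integer labels (row-wise argmax, first maximum on
#'   ties).
#' @export
oneHotToLabels <- function(m) max.col(m, ties.method = "first") - 1L

#' Min-max scale every trial to \[-1, 1\]
#'
#' Per trial and per channel, the channel minimum maps to -1 and the
#' maximum to +1; a constant channel maps to all zeros.
#'
#' @param epochs an [EpochSet-class].
#' @return The scaled [EpochSet-class].
#' @export
minmaxScale <- function(epochs) {
  d <- dim(epochs@samples)
  out <- epochs@samples
  for (i in seq_len(d[1L])) {
    for (c in seq_len(d[2L])) {
      x <- epochs@samples[i, c, ]
      lo <- min(x); hi <- max(x)
      out[i, c, ] <- if (hi > lo) 2 * (x - lo) / (hi - lo) - 1 else 0 * x
    }
  }
  epochSet(out, epochs@fs, epochs@labels, epochs@channelNames)
}

#' Run the standard preprocessing pipeline
#'
#' Applies, in the canonical order: bandpass filter, optional notch,
#' window cropping, min-max scaling.
#'
#' @param epochs an [EpochSet-class].
#' @param filter a [filterSpec()] or `NULL` to skip filtering.
#' @param notch notch frequency in Hz or `NULL`.
#' @param window `c(tStart, tEnd)` in seconds or `NULL` to keep the full
#'   trial.
#' @param scale apply [minmaxScale()] last (default `TRUE`).
#' @return The preprocessed [EpochSet-class].
#' @export
applyPipeline <- function(epochs, filter = NULL, notch = NULL,
                          window = NULL, scale = TRUE) {
  if (!is.null(filter)) epochs <- bandpassFilter(epochs, spec = filter)
  if (!is.null(notch)) epochs <- notchFilter(epochs, notch)
  if (!is.null(window)) epochs <- cropWindow(epochs, window[1L], window[2L])
  if (scale) epochs <- minmaxScale(epochs)
  epochs
}
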