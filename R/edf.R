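# Minimal EDF (European Data Format) reader/writer: fixed-width ASCII
# header (256 bytes + 256 per signal) and 16-bit little-endian samples
# with per-signal physical/digital scaling. Covers continuous multichannel
# recordings with a uniform sampling rate, which is all the epoching
# adapter needs. GDF is not handled.

readAscii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Write a continuous multichannel recording as EDF
#'
#' Samples are quantized to the 16-bit digital range against per-channel
#' physical extrema, so the round trip is exact to about 1/65535 of the
#' channel range. The recording is split into 1-second data records;
#' trailing samples short of a full second are zero-padded.
#'
#' @param data numeric `channels x samples` matrix.
#' @param fs sampling rate in Hz (must be a positive integer).
#' @param path output file path.
#' @param channelNames optional channel labels (<= 16 characters each).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(data, fs, path, channelNames = NULL) {
  data <- as.matrix(data)
  C <- nrow(data); N <- ncol(data)
  fs <- as.integer(fs)
  if (fs <= 0) stop("writeRecording: fs must be a positive integer")
  if (is.null(channelNames)) channelNames <- sprintf("EEG%03d", seq_len(C))
  nRec <- as.integer(ceiling(N / fs))
  if (nRec * fs > N)
    data <- cbind(data, matrix(0, C, nRec * fs - N))
  physMin <- apply(data, 1L, min)
  physMax <- apply(data, 1L, max)
  flat <- physMax <= physMin
  physMax[flat] <- physMin[flat] + 1
  digMin <- -32768L; digMax <- 32767L

  pad <- function(x, w) {
    x <- substr(format(x, trim = TRUE), 1L, w)
    formatC(x, width = w, flag = "-")
  }
  num <- function(x, w) pad(formatC(x, format = "g", digits = 6), w)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic", 80), pad("midecoder", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(as.character(256L + 256L * C), 8), pad("", 44),
                pad(as.character(nRec), 8), pad("1", 8),
                pad(as.character(C), 4))
  sig <- paste0(
    paste(vapply(channelNames, pad, "", w = 16), collapse = ""),
    paste(rep(pad("", 80), C), collapse = ""),
    paste(rep(pad("uV", 8), C), collapse = ""),
    paste(vapply(physMin, num, "", w = 8), collapse = ""),
    paste(vapply(physMax, num, "", w = 8), collapse = ""),
    paste(rep(pad(as.character(digMin), 8), C), collapse = ""),
    paste(rep(pad(as.character(digMax), 8), C), collapse = ""),
    paste(rep(pad("", 80), C), collapse = ""),
    paste(rep(pad(as.character(fs), 8), C), collapse = ""),
    paste(rep(pad("", 32), C), collapse = ""))
  writeBin(charToRaw(paste0(hdr, sig)), con)
  # re-read the truncated 8-char physical extrema so scaling matches read
  pmnTxt <- as.numeric(substr(num(physMin, 8), 1, 8))
  pmxTxt <- as.numeric(substr(num(physMax, 8), 1, 8))
  scl <- (digMax - digMin) / (pmxTxt - pmnTxt)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (c in seq_len(C)) {
      dig <- as.integer(round((data[c, idx] - pmnTxt[c]) * scl[c]) + digMin)
      dig <- pmin(pmax(dig, digMin), digMax)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readAscii(con, 8)                       # version
  readAscii(con, 80); readAscii(con, 80)  # patient / recording id
  readAscii(con, 8); readAscii(con, 8)    # start date / time
  readAscii(con, 8)                       # header bytes
  readAscii(con, 44)                      # reserved
  nRec <- as.integer(readAscii(con, 8))
  recDur <- as.numeric(readAscii(con, 8))
  C <- as.integer(readAscii(con, 4))
  if (is.na(C) || C < 1L) stop("readEdf: corrupted header in '", path, "'")
  fld <- function(w) vapply(seq_len(C), function(i) readAscii(con, w), "")
  labels <- fld(16); fld(80); fld(8)
  physMin <- as.numeric(fld(8)); physMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8)); digMax <- as.numeric(fld(8))
  fld(80)
  nSamp <- as.integer(fld(8))
  fld(32)
  if (length(unique(nSamp)) != 1L)
    stop("readEdf: mixed per-signal sampling rates are not supported")
  fs <- nSamp[1L] / recDur
  scl <- (physMax - physMin) / (digMax - digMin)
  data <- matrix(0, C, nRec * nSamp[1L])
  for (r in seq_len(nRec)) {
    for (c in seq_len(C)) {
      dig <- readBin(con, "integer", n = nSamp[1L], size = 2L,
                     signed = TRUE, endian = "little")
      if (length(dig) < nSamp[1L])
        stop("readEdf: truncated data record in '", path, "'")
      data[c, ((r - 1L) * nSamp[1L] + 1L):(r * nSamp[1L])] <-
        physMin[c] + (dig - digMin[c]) * scl[c]
    }
  }
  list(data = data, fs = fs, channelNames = labels)
}

#' Read a recording and cut event-locked epochs
#'
#' Reads a continuous EDF recording and cuts one trial per event using
#' the half-open window `[onset + window[1], onset + window[2])`. Event
#' codes are mapped to zero-based class labels via `codeMap` (by default,
#' sorted unique codes map to 0, 1, ...). Trials whose window extends past
#' the end of the recording are dropped with a warning reporting the count.
#'
#' @param path path to the recording.
#' @param format `"edf"` (`"gdf"` is recognized but not supported and
#'   raises a descriptive error).
#' @param events data.frame with columns `onset` (seconds) and `code`.
#' @param window `c(tStart, tEnd)` in seconds relative to each onset.
#' @param codeMap optional named vector mapping event codes to zero-based
#'   labels.
#' @return An [EpochSet-class].
#' @export
readRecording <- function(path, format = c("edf", "gdf"), events,
                          window = c(0, 1), codeMap = NULL) {
  format <- match.arg(format)
  if (format == "gdf")
    stop("readRecording: GDF is not supported; convert the recording to ",
         "EDF or epoch it externally")
  if (!file.exists(path)) stop("readRecording: no such file '", path, "'")
  if (missing(events) || is.null(events) || nrow(events) == 0L)
    stop("readRecording: no events supplied for epoching")
  rec <- readEdf(path)
  if (is.null(codeMap)) {
    codes <- sort(unique(events$code))
    codeMap <- stats::setNames(seq_along(codes) - 1L, codes)
  }
  keepEv <- as.character(events$code) %in% names(codeMap)
  if (!any(keepEv))
    stop("readRecording: no events match the supplied code map")
  events <- events[keepEv, , drop = FALSE]
  n <- round((window[2L] - window[1L]) * rec$fs)
  starts <- floor((events$onset + window[1L]) * rec$fs) + 1
  ok <- starts >= 1 & starts + n - 1 <= ncol(rec$data)
  if (any(!ok))
    warning(sprintf("readRecording: dropped %d trial(s) whose window %s",
                    sum(!ok), "extends past the recording"))
  if (!any(ok))
    stop("readRecording: every epoch window falls outside the recording")
  starts <- starts[ok]
  labs <- unname(codeMap[as.character(events$code[ok])])
  samples <- array(0, c(length(starts), nrow(rec$data), n))
  for (i in seq_along(starts))
    samples[i, , ] <- rec$data[, starts[i]:(starts[i] + n - 1)]
  epochSet(samples, rec$fs, labs, rec$channelNames)
}
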