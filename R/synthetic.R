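# Synthetic motor-imagery EEG. Class identity is carried by a narrowband
# rhythm (band-limited Gaussian noise, not a pure tone: CSP discriminates
# variance structure and a deterministic sinusoid would make the task
# degenerate) projected through a class-specific spatial pattern, on top
# of i.i.d. broadband Gaussian noise.

#' Configuration for the synthetic EEG generator
#'
#' Defaults mirror the geometry of a standard four-class motor-imagery
#' recording: 72 trials per class, 22 channels, 250 Hz, 7.5 s trials.
#' Class rhythms sit at centers spread across the mu (8-13 Hz) and beta
#' (15-30 Hz) ranges.
#'
#' @param nClasses number of classes (>= 2).
#' @param nTrialsPerClass trials generated per class.
#' @param nChannels number of EEG channels.
#' @param fs sampling rate, Hz.
#' @param trialDur trial duration, seconds.
#' @param classBands per-class `c(center, bandwidth)` in Hz: a list with
#'   one entry per class, or `NULL` for centers spread over 10-26 Hz with
#'   4 Hz bandwidth.
#' @param snr ratio of total class-rhythm power (summed over channels) to
#'   per-channel broadband noise power. `snr = 0` gives pure noise.
#' @param mixing optional `nClasses x nChannels` matrix of unit-norm
#'   spatial patterns; `NULL` draws a seed-derived orthonormal set.
#' @param seed integer seed; generation is a pure function of the full
#'   configuration including this seed.
#' @return A validated list of class `"SynthConfig"`.
#' @examples
#' cfg <- synthConfig(nClasses = 2, nTrialsPerClass = 10, nChannels = 4,
#'                    fs = 128, trialDur = 2, snr = 5, seed = 1)
#' ep <- generateEpochs(cfg)
#' ep
#' @export
synthConfig <- function(nClasses = 4, nTrialsPerClass = 72, nChannels = 22,
                        fs = 250, trialDur = 7.5, classBands = NULL,
                        snr = 1, mixing = NULL, seed = 42) {
  cfg <- list(nClasses = as.integer(nClasses),
              nTrialsPerClass = as.integer(nTrialsPerClass),
              nChannels = as.integer(nChannels), fs = as.numeric(fs),
              trialDur = as.numeric(trialDur), classBands = classBands,
              snr = as.numeric(snr), mixing = mixing,
              seed = as.integer(seed))
  if (cfg$nClasses < 2L)
    stop("synthConfig: nClasses must be >= 2")
  if (cfg$nTrialsPerClass < 1L || cfg$nChannels < 1L)
    stop("synthConfig: counts must be positive")
  if (cfg$fs <= 0 || cfg$trialDur <= 0)
    stop("synthConfig: fs and trialDur must be positive")
  if (cfg$snr < 0)
    stop("synthConfig: snr must be non-negative")
  if (is.null(cfg$classBands)) {
    centers <- seq(10, 26, length.out = cfg$nClasses)
    cfg$classBands <- lapply(centers, function(f0) c(f0, 4))
  }
  if (length(cfg$classBands) != cfg$nClasses)
    stop("synthConfig: need one classBand per class")
  for (b in cfg$classBands) {
    if (length(b) != 2L || b[1L] <= 0 || b[2L] <= 0)
      stop("synthConfig: each classBand is c(center, bandwidth), both > 0")
    if (b[1L] + b[2L] / 2 >= cfg$fs / 2)
      stop("synthConfig: class band exceeds the Nyquist frequency")
  }
  if (!is.null(cfg$mixing)) {
    cfg$mixing <- as.matrix(cfg$mixing)
    if (!all(dim(cfg$mixing) == c(cfg$nClasses, cfg$nChannels)))
      stop("synthConfig: mixing must be nClasses x nChannels")
  }
  class(cfg) <- "SynthConfig"
  cfg
}

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Band-limited unit-power Gaussian noise via an ideal FFT-domain bandpass.
bandNoise <- function(n, fs, center, bandwidth) {
  x <- rnorm(n)
  freqs <- (seq_len(n) - 1L) / n * fs
  freqs <- pmin(freqs, fs - freqs)            # two-sided spectrum
  keep <- freqs >= center - bandwidth / 2 & freqs <= center + bandwidth / 2
  X <- fft(x)
  X[!keep] <- 0
  r <- Re(fft(X, inverse = TRUE)) / n
  p <- mean(r^2)
  if (p > 0) r <- r / sqrt(p)
  r
}

#' Generate synthetic motor-imagery epochs
#'
#' Class `k` trials contain band-limited Gaussian rhythm noise in the
#' class band, projected through the class spatial pattern and scaled so
#' that total rhythm power over channels equals `snr` times the unit
#' per-channel broadband noise power. Trials are stacked class by class;
#' labels are balanced by construction. Two calls with identical
#' configurations return bit-identical arrays.
#'
#' @param config a [synthConfig()] object.
#' @return An [EpochSet-class] with `nClasses * nTrialsPerClass` trials.
#' @export
generateEpochs <- function(config) {
  if (!inherits(config, "SynthConfig"))
    stop("generateEpochs: 'config' must come from synthConfig()")
  K <- config$nClasses; C <- config$nChannels
  nT <- round(config$fs * config$trialDur)
  withSeed(config$seed, {
    mixing <- config$mixing
    if (is.null(mixing)) {
      basis <- qr.Q(qr(matrix(rnorm(C * C), C, C)))
      mixing <- t(basis[, seq_len(min(K, C)), drop = FALSE])
      if (K > C)  # more classes than channels: reuse patterns cyclically
        mixing <- mixing[((seq_len(K) - 1L) %% C) + 1L, , drop = FALSE]
    } else {
      nrm <- sqrt(rowSums(mixing^2))
      mixing <- mixing / ifelse(nrm > 0, nrm, 1)
    }
    nTot <- K * config$nTrialsPerClass
    samples <- array(0, c(nTot, C, nT))
    idx <- 0L
    for (k in seq_len(K)) {
      band <- config$classBands[[k]]
      for (tr in seq_len(config$nTrialsPerClass)) {
        idx <- idx + 1L
        noise <- matrix(rnorm(C * nT), C, nT)
        if (config$snr > 0) {
          r <- bandNoise(nT, config$fs, band[1L], band[2L])
          samples[idx, , ] <- noise +
            sqrt(config$snr) * tcrossprod(mixing[k, ], r)
        } else {
          samples[idx, , ] <- noise
        }
      }
    }
    epochSet(samples, config$fs,
             rep(seq_len(K) - 1L, each = config$nTrialsPerClass))
  })
}

#' Write / read an epoch fixture
#'
#' Lossless on-disk representation of an [EpochSet-class]: a JSON sidecar
#' `<stem>.json` (dimensions, sampling rate, labels, channel names, dtype,
#' byte order) plus a raw little-endian float64 payload `<stem>.dat` in R
#' column-major order. The round trip is bit-exact.
#'
#' @param epochs an [EpochSet-class].
#' @param path file stem; `.json` and `.dat` are appended.
#' @return `writeFixture` returns `path` invisibly; `readFixture` returns
#'   the reconstructed [EpochSet-class].
#' @export
writeFixture <- function(epochs, path) {
  stopifnot(is(epochs, "EpochSet"))
  meta <- list(format = "midecoder-epochs", version = 1L,
               dim = dim(epochs@samples), fs = epochs@fs,
               labels = epochs@labels, channelNames = epochs@channelNames,
               dtype = "float64", byteOrder = "little")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs@samples), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname writeFixture
#' @export
readFixture <- function(path) {
  jp <- paste0(path, ".json"); dp <- paste0(path, ".dat")
  if (!file.exists(jp) || !file.exists(dp))
    stop("readFixture: fixture files not found at stem '", path, "'")
  meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
  if (!identical(meta$format, "midecoder-epochs"))
    stop("readFixture: '", jp, "' is not an epoch fixture header")
  d <- as.integer(meta$dim)
  n <- prod(d)
  con <- file(dp, "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(raw) != n)
    stop("readFixture: payload truncated (expected ", n, " values, got ",
         length(raw), ")")
  epochSet(array(raw, d), meta$fs, meta$labels,
           if (is.null(meta$channelNames)) character()
           else as.character(meta$channelNames))
}
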