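# Shared fixtures, all generated in code.

# Easy two-class set: strong narrowband rhythms (mu-ish vs beta-ish) with
# orthogonal spatial patterns.
easyEpochs <- function(nPerClass = 30, nChannels = 4, fs = 128,
                       dur = 1.5, snr = 5, seed = 101) {
  generateEpochs(synthConfig(
    nClasses = 2, nTrialsPerClass = nPerClass, nChannels = nChannels,
    fs = fs, trialDur = dur,
    classBands = list(c(10, 4), c(22, 4)), snr = snr, seed = seed))
}

noiseEpochs <- function(nPerClass = 30, nChannels = 4, fs = 128,
                        dur = 1.5, seed = 202) {
  generateEpochs(synthConfig(
    nClasses = 2, nTrialsPerClass = nPerClass, nChannels = nChannels,
    fs = fs, trialDur = dur, snr = 0, seed = seed))
}

# Independent periodogram band-power oracle (raw FFT, no package code).
bandPowerOracle <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) / n * fs
  keep <- f >= band[1] & f <= band[2] & f <= fs / 2
  sum(p[keep]) / n
}

# Mean band power of an epoch set over trials of one class, averaged
# over channels.
classBandPower <- function(ep, class, band) {
  idx <- which(epochLabels(ep) == class)
  fs <- samplingRate(ep)
  mean(vapply(idx, function(i) {
    mean(vapply(seq_len(nChannels(ep)), function(c)
      bandPowerOracle(epochData(ep)[i, c, ], fs, band), 0))
  }, 0))
}

# Minimal nearest-centroid classifier on feature matrices.
centroidFit <- function(x, y) {
  lev <- sort(unique(y))
  list(lev = lev,
       mu = t(vapply(lev, function(k) colMeans(x[y == k, , drop = FALSE]),
                     numeric(ncol(x)))))
}
centroidPredict <- function(fit, x) {
  d2 <- vapply(seq_along(fit$lev), function(j)
    rowSums(sweep(x, 2L, fit$mu[j, ])^2), numeric(nrow(x)))
  fit$lev[max.col(-d2, ties.method = "first")]
}

# A pure-sinusoid epoch set (one trial, one channel) for filter tests.
sineEpochs <- function(freq, fs = 250, dur = 4) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  epochSet(array(sin(2 * pi * freq * t), c(1, 1, length(t))), fs, 0L)
}

trimmed <- function(ep, trial = 1, chan = 1, edge = NULL) {
  x <- epochData(ep)[trial, chan, ]
  n <- length(x)
  e <- if (is.null(edge)) round(samplingRate(ep)) else edge
  x[(e + 1):(n - e)]
}

rms <- function(x) sqrt(mean(x^2))
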