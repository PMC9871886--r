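test_that("bandpass filter passes in-band and rejects out-of-band sinusoids", {
  ep <- sineEpochs(20, fs = 250, dur = 4)
  inBand <- bandpassFilter(ep, low = 8, high = 30)
  expect_equal(rms(trimmed(inBand)) / rms(trimmed(ep)), 1, tolerance = 0.05)
  outBand <- bandpassFilter(ep, low = 8, high = 13)
  expect_lt(rms(trimmed(outBand)) / rms(trimmed(ep)), 0.1)
  none <- bandpassFilter(ep, spec = filterSpec("none"))
  expect_identical(epochData(none), epochData(ep))
  expect_error(bandpassFilter(ep, low = 8, high = 130), "Nyquist")
  expect_error(filterSpec("bandpass", low = 30, high = 8), "low < high")
})

test_that("notch filter suppresses the line frequency and spares neighbours", {
  at50 <- sineEpochs(50, fs = 250, dur = 4)
  expect_lt(rms(trimmed(notchFilter(at50, 50))) / rms(trimmed(at50)), 0.1)
  at10 <- sineEpochs(10, fs = 250, dur = 4)
  expect_equal(rms(trimmed(notchFilter(at10, 50))) / rms(trimmed(at10)), 1,
               tolerance = 0.05)
  dc <- epochSet(array(1, c(1, 1, 500)), 250, 0L)
  filtered <- trimmed(notchFilter(dc, 50), edge = 100)
  expect_equal(filtered, rep(1, 300), tolerance = 0.02)
  expect_error(notchFilter(at50, 200), "Nyquist")
})

test_that("filtering is linear", {
  set.seed(5)
  ep <- epochSet(array(rnorm(2 * 2 * 400), c(2, 2, 400)), 200, c(0L, 1L))
  scaled <- epochSet(3.7 * epochData(ep), 200, c(0L, 1L))
  a <- bandpassFilter(scaled, low = 4, high = 40)
  b <- bandpassFilter(ep, low = 4, high = 40)
  expect_equal(epochData(a), 3.7 * epochData(b), tolerance = 1e-10)
})

test_that("cropping keeps the half-open window with the right sample count", {
  ep <- generateEpochs(synthConfig(nClasses = 2, nTrialsPerClass = 2,
                                   nChannels = 3, fs = 250, trialDur = 7.5,
                                   snr = 0, seed = 1))
  expect_equal(nTimepoints(cropWindow(ep, 2, 6)), 1000)
  ep160 <- generateEpochs(synthConfig(nClasses = 2, nTrialsPerClass = 2,
                                      nChannels = 4, fs = 160, trialDur = 4,
                                      snr = 0, seed = 1))
  expect_equal(nTimepoints(cropWindow(ep160, 0, 3)), 480)
  full <- cropWindow(ep, 0, 7.5)
  expect_identical(epochData(full), epochData(ep))
  # half-open: [0, 1) keeps samples 0..fs-1
  expect_equal(epochData(cropWindow(ep, 0, 1))[1, 1, ],
               epochData(ep)[1, 1, 1:250])
  expect_error(cropWindow(ep, 5, 9), "tEnd")
  expect_error(cropWindow(ep, -1, 2), "tStart")
})

test_that("one-hot encoding matches the class-vector convention", {
  m <- oneHot(0:3, 4)
  expect_equal(m, diag(4))
  expect_equal(oneHot(c(0, 1, 0), 2),
               matrix(c(1, 0, 1, 0, 1, 0), 3, 2))
  expect_true(all(rowSums(m) == 1))
  expect_error(oneHot(5, 4), "labels")
  # round trip with argmax
  set.seed(8)
  labs <- sample(0:3, 50, replace = TRUE)
  expect_identical(oneHotToLabels(oneHot(labs, 4)), as.integer(labs))
})

test_that("min-max scaling maps each trial channel onto [-1, 1]", {
  a <- array(0, c(1, 2, 3))
  a[1, 1, ] <- c(0, 5, 10)
  a[1, 2, ] <- c(3, 3, 3)
  ep <- epochSet(a, 10, 0L)
  sc <- minmaxScale(ep)
  expect_equal(sc@samples[1, 1, ], c(-1, 0, 1))
  expect_equal(sc@samples[1, 2, ], c(0, 0, 0))
  set.seed(6)
  r <- minmaxScale(epochSet(array(rnorm(5 * 3 * 40, sd = 17), c(5, 3, 40)),
                            100, rep(0L, 5)))
  expect_lte(max(abs(epochData(r))), 1)
  expect_equal(max(epochData(r)), 1)
})

test_that("the pipeline applies crop before scale", {
  set.seed(7)
  ep <- epochSet(array(rnorm(2 * 2 * 300), c(2, 2, 300)), 100, c(0L, 1L))
  out <- applyPipeline(ep, window = c(1, 2))
  expect_identical(epochData(out),
                   epochData(minmaxScale(cropWindow(ep, 1, 2))))
  # the reverse order would differ (extremes outside the window)
  alt <- cropWindow(minmaxScale(ep), 1, 2)
  expect_false(identical(epochData(out), epochData(alt)))
})

test_that("EDF recordings round-trip and epoch by events", {
  set.seed(9)
  fs <- 100
  data <- matrix(rnorm(4 * fs * 10), 4)   # 10 s, 4 channels
  path <- tempfile(fileext = ".edf")
  writeRecording(data, fs, path, channelNames = paste0("C", 1:4))
  events <- data.frame(onset = c(1, 4, 7), code = c("left", "right", "left"))
  ep <- readRecording(path, "edf", events = events, window = c(0, 2))
  expect_equal(nChannels(ep), 4)
  expect_equal(samplingRate(ep), 100)
  expect_equal(nTrials(ep), 3)
  expect_equal(nTimepoints(ep), 200)
  expect_equal(epochLabels(ep), c(0L, 1L, 0L))
  expect_equal(channelNames(ep), paste0("C", 1:4))
  # 16-bit quantization: relative error small against the channel range
  expect_equal(epochData(ep)[1, 2, ], data[2, 101:300], tolerance = 1e-3)
})

test_that("EDF epoching reports dropped and missing events", {
  set.seed(10)
  path <- tempfile(fileext = ".edf")
  writeRecording(matrix(rnorm(2 * 300), 2), 100, path)
  late <- data.frame(onset = c(0.5, 2.5), code = c("a", "b"))
  expect_warning(ep <- readRecording(path, "edf", events = late,
                                     window = c(0, 1)), "dropped 1")
  expect_equal(nTrials(ep), 1)
  expect_error(readRecording(path, "edf",
                             events = data.frame(onset = 1, code = "x"),
                             window = c(0, 1), codeMap = c(y = 0L)),
               "no events match")
  expect_error(readRecording(path, "gdf",
                             events = data.frame(onset = 1, code = "x")),
               "GDF")
  expect_error(readRecording(tempfile(), "edf",
                             events = data.frame(onset = 1, code = "x")),
               "no such file")
})
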