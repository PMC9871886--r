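tinyFeatures <- function(n = 40, steps = 6, feats = 3, seed = 71) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- array(rnorm(n * steps * feats), c(n, steps, feats))
  x[y == 1, , 1] <- x[y == 1, , 1] + 2   # easy linear offset
  list(x = x, y = y)
}

test_that("training is deterministic given data, config and seeds", {
  d <- tinyFeatures()
  cfgT <- trainConfig("adam", 1e-2, 16L, 5L, seed = 72)
  run <- function() {
    m <- buildLstmDecoder(6, 3, units = c(4, 4), nClasses = 2,
                          dropout = 0.2, seed = 73)
    trainDecoder(m, d$x, d$y, cfgT)
  }
  a <- run(); b <- run()
  expect_identical(a@model@layers[[1]]$params$Wx,
                   b@model@layers[[1]]$params$Wx)
  expect_identical(a@model@layers[[7]]$params$W,
                   b@model@layers[[7]]$params$W)
  expect_identical(a@history, b@history)
})

test_that("training does not mutate the input model and records history", {
  d <- tinyFeatures()
  m <- buildLstmDecoder(6, 3, units = c(4, 4), nClasses = 2, seed = 74)
  before <- m@layers[[1]]$params$Wx
  fit <- trainDecoder(m, d$x, d$y, trainConfig("adam", 1e-2, 16L, 4L, 75),
                      valX = d$x, valY = d$y)
  expect_identical(m@layers[[1]]$params$Wx, before)
  expect_equal(nrow(fit@history), 4)
  expect_true(all(c("loss", "accuracy", "valLoss", "valAccuracy") %in%
                    names(fit@history)))
  expect_gt(fit@history$accuracy[4], fit@history$accuracy[1] - 0.05)
})

test_that("a learnable toy problem is learned by every optimizer", {
  d <- tinyFeatures(n = 60)
  for (opt in c("adam", "rmsprop", "sgd")) {
    m <- buildLstmDecoder(6, 3, units = c(6, 6), nClasses = 2, seed = 76)
    lr <- if (opt == "sgd") 0.05 else 0.01
    fit <- trainDecoder(m, d$x, d$y, trainConfig(opt, lr, 16L, 15L, 77))
    expect_gte(tail(fit@history$accuracy, 1), 0.9)
  }
})

test_that("stratified holdout splits preserve balance and partition the data", {
  ep <- generateEpochs(synthConfig(nClasses = 2, nTrialsPerClass = 50,
                                   nChannels = 2, fs = 64, trialDur = 0.5,
                                   snr = 0, seed = 78))
  sp <- holdoutSplit(ep, 0.3, seed = 78)
  expect_equal(nTrials(sp$train), 70)
  expect_equal(nTrials(sp$tune), 30)
  expect_equal(as.vector(table(epochLabels(sp$tune))), c(15, 15))
  expect_setequal(c(sp$trainIdx, sp$tuneIdx), seq_len(100))
  sp2 <- holdoutSplit(ep, 0.3, seed = 78)
  expect_identical(sp$tuneIdx, sp2$tuneIdx)
  sp3 <- holdoutSplit(ep, 0.3, seed = 79)
  expect_false(identical(sp$tuneIdx, sp3$tuneIdx))
  tiny <- ep[c(1, 51)]
  expect_error(holdoutSplit(tiny, 0.3), "fewer than 2")
  expect_error(holdoutSplit(ep, 1.2), "fraction")
})

test_that("grid search enumerates the full Cartesian products exactly once", {
  calls <- new.env(); calls$n <- 0L
  mockEval <- function(config) {
    calls$n <- calls$n + 1L
    list(accuracy = 0.5, kappa = 0)
  }
  g1 <- gridSearch(mockEval, commonHyperGrid(), stage = "common")
  expect_equal(nrow(g1@log), 1458)  # 3*3*3*3*3*6
  expect_equal(calls$n, 1458L)
  g2 <- gridSearch(mockEval, lstmHyperGrid(), stage = "specific")
  expect_equal(nrow(g2@log), 16)
  g3 <- gridSearch(mockEval, eegnetHyperGrid(), stage = "specific")
  expect_equal(nrow(g3@log), 256)
  expect_error(gridSearch(mockEval, list()), "empty grid")
})

test_that("best-configuration selection maximizes kappa with deterministic ties", {
  scripted <- data.frame(lr = c(1, 2, 3, 4),
                         accuracy = c(0.9, 0.8, 0.8, 0.9),
                         kappa = c(0.5, 0.6, 0.6, 0.5))
  best <- selectBest(scripted)
  expect_equal(best$lr, 2)   # kappa tie, equal accuracy: first occurrence
  scripted$accuracy[3] <- 0.95
  expect_equal(selectBest(scripted)$lr, 3)  # accuracy breaks the kappa tie
  # single-configuration grid returns that configuration
  one <- gridSearch(function(cfg) list(accuracy = 1, kappa = 1),
                    list(lr = 0.1, bs = 32), stage = "common")
  expect_equal(one@best$lr, 0.1)
  expect_equal(one@best$bs, 32)
})

test_that("the winning configuration is recomputable from the saved log", {
  set.seed(80)
  mockEval <- function(config)
    list(accuracy = runif(1), kappa = runif(1))
  gr <- gridSearch(mockEval, list(a = 1:4, b = c(10, 20)), stage = "common")
  re <- selectBest(gr@log)
  expect_equal(re[c("a", "b")], gr@best[c("a", "b")])
})

test_that("the trainer adapter plugs decoders into the grid search", {
  d <- tinyFeatures(n = 32)
  builder <- function(config)
    buildLstmDecoder(6, 3, units = c(config$units1, config$units1),
                     nClasses = 2, dropout = config$dropout %||% 0.1,
                     seed = 81)
  `%||%` <- midecoder:::`%||%`
  ev <- decoderEvalFn(builder, d$x, d$y, d$x, d$y, seed = 81)
  gr <- gridSearch(ev, list(units1 = c(4L, 6L)), stage = "specific",
                   fixed = list(optimizer = "adam", learningRate = 0.01,
                                batchSize = 16L, epochs = 3L))
  expect_equal(nrow(gr@log), 2)
  expect_true(all(is.finite(gr@log$kappa)))
  expect_true(gr@best$units1 %in% c(4L, 6L))
})

test_that("a non-finite loss aborts with a diagnostic", {
  d <- tinyFeatures(n = 16)
  m <- buildLstmDecoder(6, 3, units = c(4, 4), nClasses = 2, seed = 82)
  m@layers[[7]]$params$W[] <- Inf   # corrupt the readout weights
  expect_error(
    trainDecoder(m, d$x, d$y, trainConfig("sgd", 0.01, 8L, 2L, 82)),
    "non-finite")
})
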