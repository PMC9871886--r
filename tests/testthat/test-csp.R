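diagTrials <- function(sds, n = 8, len = 4000, seed = 21) {
  set.seed(seed)
  lapply(seq_len(n), function(i) diag(sds) %*% matrix(rnorm(2 * len), 2))
}

test_that("identical class covariances give no discriminative direction", {
  a <- diagTrials(c(1, 1), seed = 22)
  b <- diagTrials(c(1, 1), seed = 23)
  m <- cspFit(a, b, nPairs = 1)
  expect_equal(m@eig$DH, c(0.5, 0.5), tolerance = 0.02)
})

test_that("the 2x2 diagonal case matches the closed-form eigensystem", {
  # R_H ~ diag(4,1), R_F ~ diag(1,4): after trace normalization the
  # whitened first-class covariance has eigenvalues 0.8 and 0.2 and the
  # extreme filters align with the coordinate axes.
  m <- cspFit(diagTrials(c(2, 1), n = 12, seed = 24),
              diagTrials(c(1, 2), n = 12, seed = 25), nPairs = 1)
  expect_equal(m@eig$DH[1], 0.8, tolerance = 0.02)
  expect_equal(m@eig$DH[2], 0.2, tolerance = 0.02)
  w1 <- m@W[1, ] / sqrt(sum(m@W[1, ]^2))
  w2 <- m@W[2, ] / sqrt(sum(m@W[2, ]^2))
  expect_gt(abs(w1[1]), 0.99)   # first filter picks channel 1
  expect_gt(abs(w2[2]), 0.99)   # last filter picks channel 2
})

test_that("eigenvalue matrices of the whitened covariances sum to the identity", {
  set.seed(26)
  mix <- matrix(rnorm(16), 4)
  trials <- function(sds) lapply(1:10, function(i)
    mix %*% diag(sds) %*% matrix(rnorm(4 * 800), 4))
  m <- cspFit(trials(c(3, 2, 1, 1)), trials(c(1, 1, 2, 3)), nPairs = 2)
  expect_lt(max(abs(m@eig$DH + m@eig$DF - 1)), 1e-8)
  # W simultaneously diagonalizes both average class covariances
  A <- m@W %*% m@classCovs$RH %*% t(m@W)
  B <- m@W %*% m@classCovs$RF %*% t(m@W)
  expect_lt(max(abs(A - diag(diag(A)))), 1e-8)
  expect_lt(max(abs(B - diag(diag(B)))), 1e-8)
  # whitening: P R P' = I
  P <- m@whitener
  expect_lt(max(abs(P %*% m@composite$R %*% t(P) - diag(4))), 1e-8)
})

test_that("the leading filter maximizes the variance ratio over a direction grid", {
  set.seed(27)
  rot <- cbind(c(cos(0.6), sin(0.6)), c(-sin(0.6), cos(0.6)))
  trials <- function(sds) lapply(1:10, function(i)
    rot %*% diag(sds) %*% matrix(rnorm(2 * 1500), 2))
  h <- trials(c(2.5, 1)); f <- trials(c(1, 2))
  m <- cspFit(h, f, nPairs = 1)
  RH <- m@classCovs$RH; RF <- m@classCovs$RF
  ratio <- function(w) (w %*% RH %*% w) / (w %*% (RH + RF) %*% w)
  w1 <- m@W[1, ]
  grid <- seq(0, pi, length.out = 2001)
  best <- max(vapply(grid, function(a) ratio(c(cos(a), sin(a))), 0))
  expect_gte(as.numeric(ratio(w1 / sqrt(sum(w1^2)))), best - 1e-6)
})

test_that("log-variance features are invariant to global trial scaling", {
  set.seed(28)
  m <- cspFit(diagTrials(c(2, 1), seed = 29), diagTrials(c(1, 2), seed = 30),
              nPairs = 1)
  x <- matrix(rnorm(2 * 500), 2)
  f1 <- logVarianceFeatures(cspTransform(m, x))
  f2 <- logVarianceFeatures(cspTransform(m, 7.3 * x))
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("projection through the identity returns the trial", {
  m <- cspFit(diagTrials(c(2, 1), seed = 41), diagTrials(c(1, 2), seed = 42),
              nPairs = 1)
  m@W <- diag(2); m@selected <- 1:2
  x <- matrix(rnorm(2 * 50), 2)
  expect_equal(cspTransform(m, x), x)
})

test_that("fit and transform validate their inputs", {
  a <- diagTrials(c(1, 2), n = 1, seed = 43)
  expect_error(cspFit(a, a, 1), "at least 2 trials")
  b <- diagTrials(c(1, 2), n = 4, seed = 44)
  expect_error(cspFit(b, b, nPairs = 2), "nPairs")
  m <- cspFit(diagTrials(c(2, 1), seed = 45), diagTrials(c(1, 2), seed = 46))
  expect_error(cspTransform(m, matrix(0, 3, 10)), "channels")
})

test_that("class log-variance features separate high-snr synthetic classes", {
  ep <- easyEpochs(nPerClass = 25, snr = 5, seed = 47)
  labs <- epochLabels(ep)
  trialsOf <- function(k) lapply(which(labs == k),
                                 function(i) epochData(ep)[i, , ])
  m <- cspFit(trialsOf(0), trialsOf(1), nPairs = 1)
  f1 <- vapply(which(labs == 0), function(i)
    logVarianceFeatures(cspTransform(m, epochData(ep)[i, , ]))[1], 0)
  f2 <- vapply(which(labs == 1), function(i)
    logVarianceFeatures(cspTransform(m, epochData(ep)[i, , ]))[1], 0)
  pooled <- sqrt((var(f1) + var(f2)) / 2)
  expect_gt(abs(mean(f1) - mean(f2)) / pooled, 2)
})

test_that("the WPD-CSP extractor has the declared sequence geometry", {
  ep <- easyEpochs(nPerClass = 12, nChannels = 4, snr = 5, seed = 48)
  ex <- fitWpdCsp(ep, level = 4, nPairs = 2)
  fs <- extractWpdCsp(ex, ep)
  expect_equal(dim(fs@values), c(24, 16, 4))  # 2-class: 1 pairing x 2*2
  expect_true(all(is.finite(fs@values)))
})

test_that("the extractor transform is stateless", {
  ep <- easyEpochs(nPerClass = 10, nChannels = 4, snr = 5, seed = 49)
  ex <- fitWpdCsp(ep, level = 3, nPairs = 1)
  whole <- extractWpdCsp(ex, ep)
  part1 <- extractWpdCsp(ex, ep[1:7])
  part2 <- extractWpdCsp(ex, ep[8:20])
  expect_equal(whole@values[1:7, , ], part1@values)
  expect_equal(whole@values[8:20, , ], part2@values)
})

test_that("flattened WPD-CSP features separate held-out high-snr data", {
  ep <- easyEpochs(nPerClass = 25, nChannels = 4, snr = 5, seed = 50)
  sp <- holdoutSplit(ep, 0.3, seed = 50)
  ex <- fitWpdCsp(sp$train, level = 4, nPairs = 1)
  flat <- function(e) {
    v <- extractWpdCsp(ex, e)@values
    matrix(v, dim(v)[1], prod(dim(v)[-1]))
  }
  fit <- centroidFit(flat(sp$train), epochLabels(sp$train))
  acc <- mean(centroidPredict(fit, flat(sp$tune)) == epochLabels(sp$tune))
  expect_gte(acc, 0.9)
})

test_that("one-vs-rest banks cover every class beyond the two-class case", {
  ep <- generateEpochs(synthConfig(nClasses = 3, nTrialsPerClass = 8,
                                   nChannels = 4, fs = 128, trialDur = 1,
                                   snr = 4, seed = 51))
  ex <- fitWpdCsp(ep, level = 2, nPairs = 1)
  expect_length(ex@models[[1]], 3)
  fs <- extractWpdCsp(ex, ep)
  expect_equal(dim(fs@values), c(24, 4, 6))   # 3 pairings x 2 filters
})
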