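test_that("accuracy is the fraction of matches", {
  expect_equal(accuracyScore(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  expect_equal(accuracyScore(c(0, 1, 2, 3), c(0, 1, 0, 0)), 0.5)
  set.seed(90)
  a <- sample(0:3, 40, replace = TRUE)
  b <- sample(0:3, 40, replace = TRUE)
  expect_equal(accuracyScore(a, b), 1 - mean(a != b))  # Hamming identity
  expect_error(accuracyScore(integer(), integer()), "non-empty")
  expect_error(accuracyScore(1:3, 1:4), "equal length")
})

test_that("Cohen's kappa follows the chance-corrected formula", {
  expect_equal(cohenKappa(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  # p_o = 0.75, p_e = 0.5 -> kappa = 0.5
  expect_equal(cohenKappa(c(0, 0, 1, 1), c(0, 1, 1, 1)), 0.5)
  # chance agreement of a constant predictor on balanced labels
  expect_equal(cohenKappa(rep(0:3, each = 10), rep(0L, 40), nClasses = 4), 0)
  # independent labels: kappa near zero at large n
  set.seed(91)
  a <- sample(0:3, 4000, replace = TRUE)
  b <- sample(0:3, 4000, replace = TRUE)
  expect_lt(abs(cohenKappa(a, b)), 0.05)
  # degenerate marginals: constant and identical is perfect agreement,
  # constant but disjoint has zero expected agreement
  expect_equal(cohenKappa(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(cohenKappa(c(1, 1), c(0, 0), nClasses = 2), 0)
  expect_error(cohenKappa(c(0, 5), c(0, 1), nClasses = 4), "labels")
})

test_that("kappa equals one exactly when accuracy equals one", {
  set.seed(92)
  for (i in 1:10) {
    a <- sample(0:2, 30, replace = TRUE)
    b <- a
    if (i > 5) b[sample(30, 3)] <- sample(0:2, 3, replace = TRUE)
    acc <- accuracyScore(a, b)
    k <- cohenKappa(a, b, nClasses = 3)
    expect_equal(acc == 1, abs(k - 1) < 1e-12)
  }
})

test_that("the pinned Wilcoxon variant matches brute-force enumeration", {
  set.seed(93)
  for (rep in 1:5) {
    a <- round(runif(6), 2)
    b <- round(runif(6), 2)
    d <- round(a - b, 10); d <- d[d != 0]
    n <- length(d)
    if (n < 2) next
    w <- wilcoxonSignedRank(a, b, exact = TRUE)
    r <- rank(abs(d))
    expect_equal(w@wPlus, sum(r[d > 0]))
    # exact p by enumerating all sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wAll <- as.vector(signs %*% r)
    center <- n * (n + 1) / 4
    pEnum <- mean(abs(wAll - center) >= abs(w@wPlus - center) - 1e-12)
    expect_equal(attr(w, "pExact"), pEnum)
    expect_equal(w@nEffective, n)
  }
})

test_that("the normal-approximation p agrees with an independent implementation", {
  set.seed(94)
  a <- rnorm(12); b <- rnorm(12)
  ours <- wilcoxonSignedRank(a, b)
  ref <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE))
  expect_equal(ours@p, ref$p.value, tolerance = 1e-10)
  expect_equal(ours@wPlus, unname(ref$statistic))
})

test_that("Wilcoxon Z is antisymmetric in its arguments", {
  set.seed(95)
  a <- rnorm(10); b <- rnorm(10)
  f <- wilcoxonSignedRank(a, b)
  r <- wilcoxonSignedRank(b, a)
  expect_equal(f@z, -r@z, tolerance = 1e-12)
  expect_equal(f@p, r@p, tolerance = 1e-12)
})

test_that("degenerate Wilcoxon inputs error or warn as declared", {
  expect_error(wilcoxonSignedRank(1:5, 1:5), "no variation")
  expect_warning(wilcoxonSignedRank(c(1, 2, 3, 4), c(2, 3, 4, 5) - 0.5),
                 "fewer than 5")
  expect_error(wilcoxonSignedRank(1:4, 1:5), "equal length")
})

test_that("score summaries use the sample standard deviation", {
  st <- scoreTable(matrix(c(1, 2, 3, 4, 2, 2, 2, 2), 2, 4, byrow = TRUE,
                          dimnames = list(c("a", "b"), paste0("s", 1:4))))
  s <- summarizeScores(st, "a")
  expect_equal(unname(s["mean"]), 2.5)
  expect_equal(unname(s["sd"]), sd(1:4))
  expect_equal(unname(summarizeScores(st, "b")["sd"]), 0)
  expect_error(summarizeScores(st, "c"), "unknown method")
})

test_that("method comparison reports mean differences consistent with summaries", {
  tab <- kappaComparisonTable()
  expect_s4_class(tab, "ScoreTable")
  expect_equal(dim(scoreValues(tab)), c(6, 8))
  cmp <- compareMethods(tab, "EEGNet-LSTM")
  expect_false("EEGNet-LSTM" %in% cmp$method)
  expect_equal(nrow(cmp), 5)
  for (i in seq_len(nrow(cmp))) {
    m <- cmp$method[i]
    expect_equal(cmp$meanDiff[i],
                 unname(summarizeScores(tab, "EEGNet-LSTM")["mean"] -
                          summarizeScores(tab, m)["mean"]))
    w <- wilcoxonSignedRank(scoreValues(tab)["EEGNet-LSTM", ],
                            scoreValues(tab)[m, ])
    expect_equal(cmp$z[i], w@z)
    expect_equal(cmp$p[i], w@p)
  }
})

test_that("score tables round-trip through CSV", {
  tab <- kappaComparisonTable()
  path <- tempfile(fileext = ".csv")
  writeScoreTable(tab, path)
  back <- readScoreTable(path)
  expect_equal(scoreValues(back), scoreValues(tab))
})

test_that("decoder evaluation agrees with a confusion-matrix oracle", {
  d <- list(x = array(rnorm(30 * 4 * 2), c(30, 4, 2)),
            y = rep(0:1, 15))
  m <- buildLstmDecoder(4, 2, units = c(3, 3), nClasses = 2, seed = 96)
  res <- evaluateDecoder(m, d$x, d$y)
  pred <- predictClasses(m, d$x)
  cm <- table(factor(d$y, levels = 0:1), factor(pred, levels = 0:1))
  accOracle <- sum(diag(cm)) / sum(cm)
  peOracle <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
  expect_equal(res$accuracy, accOracle)
  expect_equal(res$kappa, (accOracle - peOracle) / (1 - peOracle))
  expect_error(evaluateDecoder(m, d$x, rep(5L, 30)), "class count")
})
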