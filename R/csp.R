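# Common spatial patterns: spatial filters that maximize the variance of
# one class while minimizing the other's, obtained by whitening the
# composite covariance and eigendecomposing the whitened class
# covariance. The two whitened class covariances share eigenvectors and
# their eigenvalue matrices sum to the identity, which is what makes the
# extreme filters discriminative.

classCovariance <- function(trials) {
  covs <- lapply(trials, function(X) {
    S <- tcrossprod(X)
    S / sum(diag(S))
  })
  Reduce(`+`, covs) / length(covs)
}

asTrialList <- function(x) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[1L]), function(i) x[i, , ]))
  stop("expected a list of channel x time matrices or a 3-D trial array")
}

#' Fit a two-class CSP model
#'
#' Computes trace-normalized spatial covariances per trial, averages them
#' within class, whitens the composite covariance and eigendecomposes the
#' whitened first-class covariance. Rows of the projection matrix `W` are
#' sorted by decreasing eigenvalue, so the first rows maximize the
#' variance ratio in favour of the first class and the last rows in
#' favour of the second; the retained filters are the first and last
#' `nPairs` rows.
#'
#' @param trialsH,trialsF trials of the two classes: lists of
#'   `channel x time` matrices or `(trial, channel, time)` arrays.
#' @param nPairs filter pairs to retain (>= 1).
#' @param eps diagonal-loading factor (times trace / channels) applied to
#'   the average covariances before decomposition, for numerical
#'   stability on short coefficient sequences.
#' @return A [CSPModel-class] carrying all intermediates.
#' @examples
#' h <- lapply(1:6, function(i) diag(c(2, 1)) %*% matrix(rnorm(200), 2))
#' f <- lapply(1:6, function(i) diag(c(1, 2)) %*% matrix(rnorm(200), 2))
#' m <- cspFit(h, f, nPairs = 1)
#' m
#' @export
cspFit <- function(trialsH, trialsF, nPairs = 1L, eps = 1e-9) {
  trialsH <- asTrialList(trialsH); trialsF <- asTrialList(trialsF)
  if (length(trialsH) < 2L || length(trialsF) < 2L)
    stop("cspFit: need at least 2 trials per class")
  C <- nrow(trialsH[[1L]])
  nPairs <- as.integer(nPairs)
  if (nPairs < 1L || 2L * nPairs > C)
    stop("cspFit: nPairs must satisfy 1 <= nPairs <= channels / 2")
  reg <- function(S) S + eps * sum(diag(S)) * diag(C) / C
  RH <- reg(classCovariance(trialsH))
  RF <- reg(classCovariance(trialsF))
  R <- RH + RF
  eR <- eigen(R, symmetric = TRUE)
  if (min(eR$values) <= max(eR$values) * 1e-12)
    stop("cspFit: composite covariance is rank-deficient even after ",
         "regularization; supply more data or more regularization")
  P <- diag(1 / sqrt(eR$values)) %*% t(eR$vectors)
  SH <- P %*% RH %*% t(P)
  SH <- (SH + t(SH)) / 2
  eS <- eigen(SH, symmetric = TRUE)          # eigenvalues descending
  U <- eS$vectors
  DH <- eS$values
  SF <- P %*% RF %*% t(P)
  DF <- diag(t(U) %*% ((SF + t(SF)) / 2) %*% U)
  W <- t(U) %*% P
  new("CSPModel", W = W, whitener = P, classCovs = list(RH = RH, RF = RF),
      composite = list(R = R, U0 = eR$vectors, D = eR$values),
      eig = list(U = U, DH = DH, DF = DF), nPairs = nPairs,
      selected = c(seq_len(nPairs), C - nPairs + seq_len(nPairs)))
}

#' Project a trial through fitted CSP filters
#'
#' @param model a [CSPModel-class].
#' @param trial `channel x time` matrix.
#' @param selectedOnly project through the retained extreme filters only
#'   (default) or through the full matrix `W`.
#' @return Matrix of projected signals `Z = W X` (one row per filter).
#' @export
cspTransform <- function(model, trial, selectedOnly = TRUE) {
  trial <- as.matrix(trial)
  if (nrow(trial) != ncol(model@W))
    stop("cspTransform: trial has ", nrow(trial), " channels but the ",
         "model was fitted on ", ncol(model@W))
  W <- if (selectedOnly) model@W[model@selected, , drop = FALSE] else model@W
  W %*% trial
}

#' Normalized log-variance features
#'
#' The classical CSP feature map: the log of each projected signal's
#' variance normalized by the total variance over the selected filters.
#' Invariant to global rescaling of the trial.
#'
#' @param z projected signals (rows = filters), e.g. from
#'   [cspTransform()].
#' @return Numeric feature vector, one value per filter.
#' @export
logVarianceFeatures <- function(z) {
  v <- apply(z, 1L, stats::var)
  v <- pmax(v, .Machine$double.xmin)  # guard degenerate constant rows
  log(v / sum(v))
}

# Fit one CSP bank per class pairing: a single two-class model when
# K == 2, otherwise one-vs-rest per class (the standard multiclass CSP
# extension of FBCSP-era pipelines).
fitCspBanks <- function(trials, labels, nPairs, eps = 1e-9) {
  classes <- sort(unique(labels))
  K <- length(classes)
  if (K < 2L) stop("CSP needs at least two classes")
  if (K == 2L) {
    list(cspFit(trials[labels == classes[1L]],
                trials[labels == classes[2L]], nPairs, eps))
  } else {
    lapply(classes, function(k)
      cspFit(trials[labels == k], trials[labels != k], nPairs, eps))
  }
}

#' Fit the WPD + CSP sequence feature extractor
#'
#' Decomposes every channel of every training trial with a level-`level`
#' wavelet packet transform, and fits one CSP filter bank per leaf node
#' (frequency order) on that node's coefficient signals — one two-class
#' bank, or one one-vs-rest bank per class when there are more than two
#' classes.
#'
#' @param epochs training [EpochSet-class] (fit on training data only).
#' @param level WPD depth; the LSTM sequence has `2^level` steps.
#' @param nPairs CSP filter pairs per bank.
#' @param wavelet wavelet family name (see [waveletFilters()]).
#' @param eps covariance regularization passed to [cspFit()].
#' @return A [WpdCspExtractor-class].
#' @seealso [extractWpdCsp()]
#' @export
fitWpdCsp <- function(epochs, level = 4L, nPairs = 1L, wavelet = "db4",
                      eps = 1e-9) {
  stopifnot(is(epochs, "EpochSet"))
  labels <- epochs@labels
  nodeTrials <- leafSignals(epochs, level, wavelet)
  models <- lapply(nodeTrials, fitCspBanks, labels = labels,
                   nPairs = nPairs, eps = eps)
  new("WpdCspExtractor", level = as.integer(level), wavelet = wavelet,
      nPairs = as.integer(nPairs),
      nClasses = length(unique(labels)), models = models)
}

# For each leaf node (frequency order), the list over trials of
# channel x coefficient matrices.
leafSignals <- function(epochs, level, wavelet) {
  filters <- waveletFilters(wavelet)
  d <- dim(epochs@samples)
  nLeaves <- 2L^level
  out <- lapply(seq_len(nLeaves), function(j) vector("list", d[1L]))
  for (i in seq_len(d[1L])) {
    perChan <- lapply(seq_len(d[2L]), function(c)
      wpdLeaves(wpdDecompose(epochs@samples[i, c, ], filters, level),
                order = "frequency"))
    for (j in seq_len(nLeaves)) {
      out[[j]][[i]] <- do.call(rbind, lapply(perChan, `[[`, j))
    }
  }
  out
}

#' Extract WPD + CSP sequence features
#'
#' Applies a fitted extractor to any epoch set: each trial yields a
#' sequence with one step per leaf node (frequency order), whose feature
#' vector concatenates the normalized log-variance CSP features of every
#' class pairing. The transform is stateless — it never re-fits, so
#' transforming disjoint batches equals transforming their union.
#'
#' @param extractor a fitted [WpdCspExtractor-class] from [fitWpdCsp()].
#' @param epochs an [EpochSet-class] with the same channel count as the
#'   training data.
#' @return A [FeatureSequence-class] of dimension
#'   `trials x 2^level x (pairings * 2 * nPairs)`.
#' @export
extractWpdCsp <- function(extractor, epochs) {
  stopifnot(is(extractor, "WpdCspExtractor"), is(epochs, "EpochSet"))
  if (length(extractor@models) == 0L)
    stop("extractWpdCsp: extractor has not been fitted")
  nodeTrials <- leafSignals(epochs, extractor@level, extractor@wavelet)
  n <- nTrials(epochs)
  nSteps <- 2L^extractor@level
  nFeat <- length(extractor@models[[1L]]) * 2L * extractor@nPairs
  values <- array(0, c(n, nSteps, nFeat))
  for (j in seq_len(nSteps)) {
    banks <- extractor@models[[j]]
    for (i in seq_len(n)) {
      feats <- unlist(lapply(banks, function(m)
        logVarianceFeatures(cspTransform(m, nodeTrials[[j]][[i]]))))
      values[i, j, ] <- feats
    }
  }
  new("FeatureSequence", values = values,
      stepSemantics = "WPD leaf nodes in frequency order")
}
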