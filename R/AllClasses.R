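#' @import methods
#' @importFrom stats var sd rnorm runif fft pnorm predict
NULL

#' Labelled multichannel EEG trials
#'
#' `EpochSet` is the central container of the package: a stack of epoched
#' EEG trials sharing a channel layout and sampling rate, with one class
#' label per trial. Samples are stored as a three-dimensional array in
#' trial x channel x time order. Labels are zero-based integer class codes
#' (the convention of the motor-imagery decoding literature, where class 0
#' is "left hand" etc.).
#'
#' @slot samples numeric array of dimension `(trial, channel, time)`.
#' @slot fs sampling rate in Hz.
#' @slot labels integer vector of zero-based class codes, one per trial.
#' @slot channelNames character vector of channel names (may be empty).
#'
#' @seealso [epochSet()] for the user constructor, [generateEpochs()] to
#'   simulate trials, [readFixture()] / [writeFixture()] for disk I/O.
#' @export
setClass("EpochSet",
  representation(
    samples = "array",
    fs = "numeric",
    labels = "integer",
    channelNames = "character"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@samples)
  if (length(d) != 3L)
    return("'samples' must be a (trial, channel, time) array")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("'fs' must be a single positive number")
  if (length(object@labels) != d[1L])
    return("length(labels) must equal the number of trials")
  if (any(object@labels < 0L, na.rm = TRUE))
    return("labels are zero-based class codes and must be >= 0")
  if (length(object@channelNames) &&
      length(object@channelNames) != d[2L])
    return("channelNames must be empty or one name per channel")
  TRUE
})

#' Construct an EpochSet
#'
#' @param samples numeric array `(trial, channel, time)`.
#' @param fs sampling rate in Hz.
#' @param labels zero-based integer class codes, one per trial.
#' @param channelNames optional channel names.
#' @return An [EpochSet-class] object.
#' @examples
#' x <- array(rnorm(4 * 3 * 100), c(4, 3, 100))
#' ep <- epochSet(x, fs = 100, labels = c(0, 0, 1, 1))
#' nTrials(ep)
#' @export
epochSet <- function(samples, fs, labels, channelNames = character()) {
  new("EpochSet", samples = samples, fs = as.numeric(fs),
      labels = as.integer(labels), channelNames = as.character(channelNames))
}

#' Wavelet packet coefficient tree
#'
#' Holds the full wavelet packet decomposition of a single signal down to
#' `level`. `coeffs[[i + 1]]` is a list of the `2^i` node coefficient
#' vectors at level `i`, in natural (filter-recursion) order; node 0 of
#' level 0 is the input signal itself.
#'
#' @slot coeffs list of per-level lists of numeric coefficient vectors.
#' @slot level integer decomposition depth.
#' @slot wavelet name of the wavelet family used.
#' @seealso [wpdDecompose()], [wpdNode()], [wpdLeaves()]
#' @export
setClass("WPDTree",
  representation(coeffs = "list", level = "integer", wavelet = "character")
)

setValidity("WPDTree", function(object) {
  if (length(object@coeffs) != object@level + 1L)
    return("coeffs must hold one list per level 0..level")
  for (i in seq_along(object@coeffs)) {
    if (length(object@coeffs[[i]]) != 2L^(i - 1L))
      return(sprintf("level %d must have %d nodes", i - 1L, 2L^(i - 1L)))
  }
  TRUE
})

#' Fitted common spatial pattern model
#'
#' Stores the full CSP projection matrix together with every intermediate
#' of the fit (normalized class covariances, composite eigendecomposition,
#' whitening matrix, whitened-covariance eigensystem), so the algebraic
#' identities of the method (D_H + D_F = I, simultaneous diagonalization)
#' can be verified on any fitted object.
#'
#' @slot W full projection matrix; rows are spatial filters sorted by
#'   decreasing eigenvalue of the whitened first-class covariance.
#' @slot whitener whitening matrix `P = D^{-1/2} U0'`.
#' @slot classCovs list with `RH`, `RF`: trial-averaged trace-normalized
#'   spatial covariances of the two classes.
#' @slot composite list with `R`, `U0`, `D`: composite covariance and its
#'   eigendecomposition.
#' @slot eig list with `U`, `DH`, `DF`: shared eigenvectors of the whitened
#'   class covariances and both diagonal eigenvalue vectors.
#' @slot nPairs number of filter pairs retained for feature extraction.
#' @slot selected integer row indices of `W` kept (first and last `nPairs`).
#' @seealso [cspFit()], [cspTransform()], [logVarianceFeatures()]
#' @export
setClass("CSPModel",
  representation(
    W = "matrix",
    whitener = "matrix",
    classCovs = "list",
    composite = "list",
    eig = "list",
    nPairs = "integer",
    selected = "integer"
  )
)

#' Fitted WPD + CSP sequence feature extractor
#'
#' One CSP filter bank per wavelet-packet leaf node (and, for more than
#' two classes, per one-vs-rest class pairing). Transforming an epoch set
#' yields a [FeatureSequence-class] whose step axis runs over the leaf
#' nodes in frequency order.
#'
#' @slot level WPD depth (the sequence has `2^level` steps).
#' @slot wavelet wavelet family name.
#' @slot nPairs CSP filter pairs per bank.
#' @slot nClasses number of classes seen at fit time.
#' @slot models list (one entry per leaf node, frequency order) of lists of
#'   [CSPModel-class] objects (one per class pairing).
#' @seealso [fitWpdCsp()], [extractWpdCsp()]
#' @export
setClass("WpdCspExtractor",
  representation(
    level = "integer",
    wavelet = "character",
    nPairs = "integer",
    nClasses = "integer",
    models = "list"
  )
)

#' Sequence features for the LSTM decoder
#'
#' @slot values numeric array `(trial, step, feature)`.
#' @slot stepSemantics description of the step axis (leaf nodes in
#'   frequency order for WPD + CSP features).
#' @export
setClass("FeatureSequence",
  representation(values = "array", stepSemantics = "character")
)

setValidity("FeatureSequence", function(object) {
  if (length(dim(object@values)) != 3L)
    return("'values' must be a (trial, step, feature) array")
  if (!all(is.finite(object@values)))
    return("feature values must be finite")
  TRUE
})

#' A neural decoder (architecture + weights)
#'
#' Layer objects are mutable environments holding parameters, gradients
#' and forward/backward closures; use [predictProba()] for inference and
#' [trainDecoder()] for fitting. Two kinds are provided: `"lstm"` (the
#' WPD-CSP sequence decoder head) and `"eegnet_lstm"` (EEGNet convolutional
#' blocks feeding the same two-layer LSTM head).
#'
#' @slot kind `"lstm"` or `"eegnet_lstm"`.
#' @slot layers list of layer environments, applied in order.
#' @slot nClasses number of output classes.
#' @slot inputShape expected input dimensions (without the trial axis).
#' @slot spec list of the hyperparameters used to build the network.
#' @export
setClass("NeuralDecoder",
  representation(
    kind = "character",
    layers = "list",
    nClasses = "integer",
    inputShape = "integer",
    spec = "list"
  )
)

#' A trained decoder with its training history
#'
#' @slot model the fitted [NeuralDecoder-class].
#' @slot history data.frame with one row per epoch (loss, accuracy and,
#'   when validation data were supplied, valLoss / valAccuracy).
#' @slot config the training configuration used (see [trainConfig()]).
#' @export
setClass("TrainedDecoder",
  representation(model = "NeuralDecoder", history = "data.frame",
                 config = "list")
)

#' Grid search result
#'
#' @slot log data.frame with one row per evaluated configuration
#'   (hyperparameter columns plus `accuracy` and `kappa`).
#' @slot best named list: the winning configuration.
#' @slot stage `"common"` or `"specific"`.
#' @seealso [gridSearch()], [selectBest()]
#' @export
setClass("GridResult",
  representation(log = "data.frame", best = "list", stage = "character")
)

#' Per-subject, per-method score table
#'
#' A methods x subjects matrix of kappa (or accuracy) values feeding the
#' summary statistics and paired Wilcoxon comparisons.
#'
#' @slot values numeric matrix, rownames = method names, colnames =
#'   subject identifiers.
#' @seealso [scoreTable()], [summarizeScores()], [compareMethods()],
#'   [kappaComparisonTable()]
#' @export
setClass("ScoreTable", representation(values = "matrix"))

setValidity("ScoreTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("score values must be numeric")
  if (anyNA(v)) return("score table must have no missing cells")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("score table needs method rownames and subject colnames")
  TRUE
})

#' Construct a ScoreTable
#'
#' @param values numeric matrix (methods x subjects) with dimnames, or a
#'   data.frame whose first column holds method names.
#' @return A [ScoreTable-class].
#' @export
scoreTable <- function(values) {
  if (is.data.frame(values)) {
    m <- as.matrix(values[, -1, drop = FALSE])
    rownames(m) <- as.character(values[[1]])
    values <- m
  }
  new("ScoreTable", values = values)
}

#' Paired Wilcoxon signed-rank result
#'
#' @slot z normal-approximation statistic.
#' @slot p two-sided p-value.
#' @slot nEffective number of pairs after zero-difference removal.
#' @slot wPlus sum of the ranks of positive differences.
#' @seealso [wilcoxonSignedRank()]
#' @export
setClass("WilcoxonResult",
  representation(z = "numeric", p = "numeric", nEffective = "integer",
                 wPlus = "numeric")
)
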