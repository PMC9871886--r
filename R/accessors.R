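# Accessors and show methods for the core containers.

#' @describeIn EpochSet-class number of trials
#' @param x,object an `EpochSet`
#' @export
nTrials <- function(x) dim(x@samples)[1L]

#' @describeIn EpochSet-class number of channels
#' @export
nChannels <- function(x) dim(x@samples)[2L]

#' @describeIn EpochSet-class number of time samples per trial
#' @export
nTimepoints <- function(x) dim(x@samples)[3L]

#' @describeIn EpochSet-class the sample array `(trial, channel, time)`
#' @export
epochData <- function(x) x@samples

#' @describeIn EpochSet-class sampling rate in Hz
#' @export
samplingRate <- function(x) x@fs

#' @describeIn EpochSet-class zero-based class labels
#' @export
epochLabels <- function(x) x@labels

#' @describeIn EpochSet-class channel names (possibly empty)
#' @export
channelNames <- function(x) x@channelNames

#' Subset an EpochSet by trial index
#'
#' @param x an `EpochSet`; @param i trial indices; @param j,...,drop ignored.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  epochSet(x@samples[i, , , drop = FALSE], x@fs, x@labels[i],
           x@channelNames)
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@samples)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], object@fs))
  tab <- table(object@labels)
  cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab),
                          collapse = ", "), "\n")
})

setMethod("show", "CSPModel", function(object) {
  cat(sprintf("CSPModel: %d channels, %d filter pair(s) retained\n",
              ncol(object@W), object@nPairs))
  dh <- object@eig$DH
  cat("  leading/trailing eigenvalues of S_H:",
      sprintf("%.3f", dh[1L]), "/", sprintf("%.3f", dh[length(dh)]), "\n")
})

setMethod("show", "WPDTree", function(object) {
  cat(sprintf("WPDTree (%s): depth %d, %d leaves of length %d\n",
              object@wavelet, object@level, 2L^object@level,
              length(object@coeffs[[object@level + 1L]][[1L]])))
})

setMethod("show", "WpdCspExtractor", function(object) {
  cat(sprintf(
    "WpdCspExtractor: level-%d WPD (%s), %d leaf nodes, %d class(es), %d CSP pair(s)\n",
    object@level, object@wavelet, 2L^object@level, object@nClasses,
    object@nPairs))
})

setMethod("show", "FeatureSequence", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureSequence: %d trials x %d steps x %d features (%s)\n",
              d[1L], d[2L], d[3L], object@stepSemantics))
})

setMethod("show", "NeuralDecoder", function(object) {
  cat(sprintf("NeuralDecoder <%s>: %d classes, %d layers, %d parameters\n",
              object@kind, object@nClasses, length(object@layers),
              countParameters(object)))
})

setMethod("show", "TrainedDecoder", function(object) {
  h <- object@history
  cat(sprintf("TrainedDecoder <%s>: %d epochs", object@model@kind, nrow(h)))
  if (nrow(h)) {
    cat(sprintf(", final loss %.4f, accuracy %.3f", h$loss[nrow(h)],
                h$accuracy[nrow(h)]))
    if ("valAccuracy" %in% names(h))
      cat(sprintf(", val accuracy %.3f", h$valAccuracy[nrow(h)]))
  }
  cat("\n")
})

setMethod("show", "GridResult", function(object) {
  cat(sprintf("GridResult (stage %s): %d configurations evaluated\n",
              object@stage, nrow(object@log)))
  cat("  best:", paste(names(object@best), unlist(object@best), sep = "=",
                       collapse = " "), "\n")
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable: %d methods x %d subjects\n",
              nrow(object@values), ncol(object@values)))
  print(round(object@values, 3))
})

setMethod("show", "WilcoxonResult", function(object) {
  cat(sprintf("Wilcoxon signed-rank: Z = %.3f, p = %.3f (n = %d, W+ = %g)\n",
              object@z, object@p, object@nEffective, object@wPlus))
})

#' Method names of a score table
#' @param x a [ScoreTable-class]
#' @export
scoreMethods <- function(x) rownames(x@values)

#' Subject identifiers of a score table
#' @param x a [ScoreTable-class]
#' @export
scoreSubjects <- function(x) colnames(x@values)

#' Score matrix of a score table
#' @param x a [ScoreTable-class]
#' @export
scoreValues <- function(x) x@values
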