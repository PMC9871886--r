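# Decoder architectures: the two-layer LSTM head used by both decoders,
# the EEGNet convolutional blocks, and their composition.

#' EEGNet architecture configuration
#'
#' @param C number of EEG channels.
#' @param T number of time samples per trial.
#' @param F1 temporal filters.
#' @param D spatial filters learned per temporal filter.
#' @param F2 pointwise filters of the separable convolution.
#' @param LK temporal kernel length of the first convolution.
#' @param nClasses output classes.
#' @param dropout dropout rate applied after each pooling stage.
#' @return A validated list of class `"EEGNetConfig"`.
#' @export
eegnetConfig <- function(C, T, F1 = 8L, D = 2L, F2 = 16L, LK = 64L,
                         nClasses = 4L, dropout = 0.25) {
  cfg <- list(C = as.integer(C), T = as.integer(T), F1 = as.integer(F1),
              D = as.integer(D), F2 = as.integer(F2), LK = as.integer(LK),
              nClasses = as.integer(nClasses), dropout = dropout)
  if (any(unlist(cfg[c("C", "T", "F1", "D", "F2", "LK", "nClasses")]) < 1L))
    stop("eegnetConfig: all architecture sizes must be positive")
  if (cfg$T < 32L)
    stop("eegnetConfig: T must be >= 32 (two pooling stages divide the ",
         "time axis by 32)")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("eegnetConfig: dropout must lie in [0, 1)")
  class(cfg) <- "EEGNetConfig"
  cfg
}

# The two-layer LSTM classification head shared by both decoders:
# LSTM -> batch-norm -> dropout -> LSTM -> batch-norm -> dropout ->
# dense(nClasses). Batch normalization of the sequence-returning layer is
# per-feature over the flattened (batch x step) axis.
lstmHeadLayers <- function(inputFeatures, units, nClasses, dropout, l2) {
  list(
    lstmLayer(inputFeatures, units[1L], returnSequences = TRUE, l2 = l2),
    batchNormLayer(units[1L], mode = "seq"),
    dropoutLayer(dropout),
    lstmLayer(units[1L], units[2L], returnSequences = FALSE, l2 = l2),
    batchNormLayer(units[2L], mode = "cols"),
    dropoutLayer(dropout),
    denseLayer(units[2L], nClasses, l2 = l2)
  )
}

#' Build the sequence LSTM decoder
#'
#' The classifier that consumes WPD + CSP sequence features: two LSTM
#' layers (each followed by batch normalization and dropout) and a dense
#' softmax output layer.
#'
#' @param inputSteps sequence length (16 for a level-4 WPD).
#' @param inputFeatures features per step.
#' @param units hidden sizes of the two LSTM layers.
#' @param nClasses output classes.
#' @param dropout dropout rate after each LSTM block.
#' @param l2 L2 penalty on the LSTM kernels and the dense layer.
#' @param seed seed for the weight initialization.
#' @return A [NeuralDecoder-class] of kind `"lstm"`.
#' @export
buildLstmDecoder <- function(inputSteps, inputFeatures, units = c(32L, 32L),
                             nClasses, dropout = 0.2, l2 = 0, seed = 42L) {
  stopifnot(inputSteps >= 1L, inputFeatures >= 1L, nClasses >= 2L)
  layers <- withSeed(seed,
    lstmHeadLayers(inputFeatures, units, nClasses, dropout, l2))
  new("NeuralDecoder", kind = "lstm", layers = layers,
      nClasses = as.integer(nClasses),
      inputShape = as.integer(c(inputSteps, inputFeatures)),
      spec = list(units = units, dropout = dropout, l2 = l2, seed = seed))
}

eegnetBlockLayers <- function(cfg) {
  list(
    tempConvLayer(cfg$LK, cfg$F1),
    batchNormLayer(cfg$F1, mode = "maps"),
    depthwiseConvLayer(cfg$C, cfg$F1, cfg$D, maxNorm = 1),
    batchNormLayer(cfg$F1 * cfg$D, mode = "maps"),
    eluLayer(),
    avgPoolLayer(4L),
    dropoutLayer(cfg$dropout),
    sepConvLayer(cfg$F1 * cfg$D, cfg$F2, kernel = 16L),
    batchNormLayer(cfg$F2, mode = "maps"),
    eluLayer(),
    avgPoolLayer(8L),
    dropoutLayer(cfg$dropout)
  )
}

#' Build the EEGNet feature-extraction blocks
#'
#' Block 1: temporal convolution (`F1` filters, kernel `1 x LK`, same
#' padding, linear) -> batch-norm -> depthwise spatial convolution (`D`
#' filters per temporal map, kernel `C x 1`, valid) -> batch-norm -> ELU
#' -> average-pool `1 x 4` -> dropout. Block 2: separable convolution
#' (`F2` filters, kernel `1 x 16`, same) -> batch-norm -> ELU ->
#' average-pool `1 x 8` -> dropout. The output has `F2` maps over
#' `(T %/% 4) %/% 8` time steps.
#'
#' @param cfg an [eegnetConfig()].
#' @param seed seed for weight initialization.
#' @return A list of class `"EegnetBlocks"` with elements `layers`,
#'   `cfg`, `outMaps`, `outSteps` and `flatLength` (`F2 * (T %/% 32)`).
#' @export
buildEegnetBlocks <- function(cfg, seed = 42L) {
  stopifnot(inherits(cfg, "EEGNetConfig"))
  layers <- withSeed(seed, eegnetBlockLayers(cfg))
  outSteps <- (cfg$T %/% 4L) %/% 8L
  structure(list(layers = layers, cfg = cfg, outMaps = cfg$F2,
                 outSteps = outSteps, flatLength = cfg$F2 * outSteps),
            class = "EegnetBlocks")
}

#' Forward pass through EEGNet blocks
#'
#' @param blocks an [buildEegnetBlocks()] object.
#' @param x `(batch, C, T)` array of trials.
#' @param flatten return a `(batch, F2 * steps)` matrix instead of the
#'   `(batch, F2, steps)` map array.
#' @param training propagate in training mode (dropout active).
#' @return Feature array or matrix.
#' @export
eegnetFeatures <- function(blocks, x, flatten = TRUE, training = FALSE) {
  for (layer in blocks$layers) x <- layerForward(layer, x, training)
  if (flatten) matrix(x, dim(x)[1L], prod(dim(x)[-1L])) else x
}

#' Build the EEGNet-LSTM decoder
#'
#' The two EEGNet blocks followed by a reshape that turns the pooled time
#' axis into a sequence of `T %/% 32` steps with `F2` features each, fed
#' into the two-layer LSTM head with a dense softmax output.
#'
#' @param cfg an [eegnetConfig()].
#' @param lstmUnits hidden sizes of the two LSTM layers.
#' @param dropout dropout rate in the LSTM head (the EEGNet blocks use
#'   `cfg$dropout`).
#' @param l2 L2 penalty on LSTM kernels and the dense layer.
#' @param seed seed for weight initialization.
#' @return A [NeuralDecoder-class] of kind `"eegnet_lstm"`.
#' @export
buildEegnetLstm <- function(cfg, lstmUnits = c(32L, 32L), dropout = 0.2,
                            l2 = 0, seed = 42L) {
  stopifnot(inherits(cfg, "EEGNetConfig"))
  if (cfg$T %/% 32L < 1L)
    stop("buildEegnetLstm: T < 32 leaves an empty LSTM sequence")
  layers <- withSeed(seed, c(
    eegnetBlockLayers(cfg),
    list(toSequenceLayer()),
    lstmHeadLayers(cfg$F2, lstmUnits, cfg$nClasses, dropout, l2)
  ))
  new("NeuralDecoder", kind = "eegnet_lstm", layers = layers,
      nClasses = cfg$nClasses, inputShape = c(cfg$C, cfg$T),
      spec = list(eegnet = cfg, lstmUnits = lstmUnits, dropout = dropout,
                  l2 = l2, seed = seed))
}

# Coerce supported inputs to the array a decoder consumes.
decoderInput <- function(model, x) {
  if (is(x, "FeatureSequence")) x <- x@values
  if (is(x, "EpochSet")) x <- x@samples
  if (length(dim(x)) != 3L)
    stop("decoder input must be a 3-D array (trials first)")
  x
}

#' Class probabilities from a decoder
#'
#' Runs a forward pass in inference mode (dropout off, batch-norm using
#' running statistics) and applies the softmax. Rows sum to one.
#'
#' @param model a [NeuralDecoder-class] (or [TrainedDecoder-class]).
#' @param x input trials: a `(batch, C, T)` array / [EpochSet-class] for
#'   `"eegnet_lstm"`, a `(batch, steps, features)` array /
#'   [FeatureSequence-class] for `"lstm"`.
#' @return `(batch, nClasses)` probability matrix.
#' @export
predictProba <- function(model, x) {
  if (is(model, "TrainedDecoder")) model <- model@model
  x <- decoderInput(model, x)
  for (layer in model@layers) x <- layerForward(layer, x, training = FALSE)
  softmaxRows(x)
}

#' Predicted class labels (zero-based)
#'
#' @inheritParams predictProba
#' @return Integer vector of zero-based class predictions.
#' @export
predictClasses <- function(model, x) oneHotToLabels(predictProba(model, x))

#' Number of trainable parameters of a decoder
#'
#' @param model a [NeuralDecoder-class] or [TrainedDecoder-class].
#' @return Integer parameter count (weights, biases, batch-norm scale and
#'   shift).
#' @export
countParameters <- function(model) {
  if (is(model, "TrainedDecoder")) model <- model@model
  sum(vapply(model@layers,
             function(l) sum(vapply(l$params, length, 0L)), 0L))
}
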