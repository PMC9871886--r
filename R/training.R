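# Training loop and exhaustive hyperparameter grid search.

#' Training configuration
#'
#' @param optimizer `"adam"`, `"rmsprop"` or `"sgd"` (plain gradient
#'   descent, no momentum).
#' @param learningRate step size.
#' @param batchSize minibatch size.
#' @param epochs fixed number of passes over the training set (no early
#'   stopping).
#' @param seed seed controlling shuffling and dropout; together with the
#'   build seed it makes training fully reproducible.
#' @return A list of class `"TrainConfig"`.
#' @export
trainConfig <- function(optimizer = "adam", learningRate = 1e-3,
                        batchSize = 32L, epochs = 100L, seed = 42L) {
  structure(list(optimizer = optimizer,
                 learningRate = as.numeric(learningRate),
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Train a decoder
#'
#' Minimizes softmax cross-entropy (plus any L2 penalties configured at
#' build time) with the configured optimizer for a fixed number of
#' epochs. The input model is not modified; a trained copy is returned.
#' All randomness (shuffling, dropout masks) derives from `config$seed`,
#' so identical data + config + seed give identical final weights.
#'
#' @param model a [NeuralDecoder-class].
#' @param x training inputs (array, [EpochSet-class] or
#'   [FeatureSequence-class] matching the decoder kind).
#' @param y one-hot label matrix or zero-based label vector.
#' @param config a [trainConfig()].
#' @param valX,valY optional validation data evaluated after each epoch.
#' @return A [TrainedDecoder-class] with the per-epoch history.
#' @export
trainDecoder <- function(model, x, y, config = trainConfig(),
                         valX = NULL, valY = NULL) {
  stopifnot(is(model, "NeuralDecoder"))
  x <- decoderInput(model, x)
  if (is.null(dim(y))) y <- oneHot(y, model@nClasses)
  n <- dim(x)[1L]
  if (nrow(y) != n) stop("trainDecoder: x and y disagree on trial count")
  layers <- cloneLayers(model@layers)
  opt <- makeOptimizer(config$optimizer, config$learningRate)
  if (!is.null(valX)) {
    valX <- decoderInput(model, valX)
    if (is.null(dim(valY))) valY <- oneHot(valY, model@nClasses)
  }
  hist <- vector("list", config$epochs)
  withSeed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batchSize)
      epLoss <- 0; epHit <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batchSize - 1L, n)]
        xb <- x[idx, , , drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        out <- xb
        for (layer in layers) out <- layerForward(layer, out, training = TRUE)
        probs <- softmaxRows(out)
        loss <- -mean(rowSums(yb * log(probs + 1e-12))) + l2Penalty(layers)
        if (!is.finite(loss))
          stop("trainDecoder: loss became non-finite at epoch ", ep,
               " (try a lower learning rate)")
        epLoss <- epLoss + loss * length(idx)
        epHit <- epHit + sum(oneHotToLabels(probs) == oneHotToLabels(yb))
        dout <- (probs - yb) / length(idx)
        for (layer in rev(layers)) dout <- layerBackward(layer, dout)
        addL2Grads(layers)
        optimizerStep(opt, layers)
      }
      row <- data.frame(epoch = ep, loss = epLoss / n, accuracy = epHit / n)
      if (!is.null(valX)) {
        vout <- valX
        for (layer in layers) vout <- layerForward(layer, vout,
                                                   training = FALSE)
        vprobs <- softmaxRows(vout)
        row$valLoss <- -mean(rowSums(valY * log(vprobs + 1e-12)))
        row$valAccuracy <- mean(oneHotToLabels(vprobs) ==
                                  oneHotToLabels(valY))
      }
      hist[[ep]] <- row
    }
  })
  trained <- new("NeuralDecoder", kind = model@kind, layers = layers,
                 nClasses = model@nClasses, inputShape = model@inputShape,
                 spec = model@spec)
  new("TrainedDecoder", model = trained, history = do.call(rbind, hist),
      config = unclass(config))
}

#' Stratified holdout split
#'
#' Splits an epoch set into a training part and a tuning/validation part,
#' drawing `round(fraction * n_k)` trials from every class `k` so class
#' balance is preserved. The two parts partition the input; the split is
#' a pure function of the seed.
#'
#' @param epochs an [EpochSet-class].
#' @param fraction fraction per class assigned to the tuning part.
#' @param seed RNG seed.
#' @return List with [EpochSet-class] elements `train` and `tune`, plus
#'   the index vectors `trainIdx` and `tuneIdx`.
#' @export
holdoutSplit <- function(epochs, fraction = 0.3, seed = 42L) {
  stopifnot(is(epochs, "EpochSet"))
  if (fraction <= 0 || fraction >= 1)
    stop("holdoutSplit: fraction must lie strictly between 0 and 1")
  labels <- epochs@labels
  tuneIdx <- withSeed(seed, {
    unlist(lapply(sort(unique(labels)), function(k) {
      ki <- which(labels == k)
      if (length(ki) < 2L)
        stop("holdoutSplit: class ", k, " has fewer than 2 trials")
      nTune <- max(1L, round(fraction * length(ki)))
      sort(sample(ki, nTune))
    }))
  })
  tuneIdx <- sort(tuneIdx)
  trainIdx <- setdiff(seq_along(labels), tuneIdx)
  list(train = epochs[trainIdx], tune = epochs[tuneIdx],
       trainIdx = trainIdx, tuneIdx = tuneIdx)
}

#' The standard hyperparameter grids
#'
#' `commonHyperGrid()` is the search space shared by both decoders
#' (optimizer, learning rate, batch size, L2, dropout, epochs: 1458
#' combinations). `lstmHyperGrid()` covers the LSTM layer sizes (16
#' combinations) and `eegnetHyperGrid()` the EEGNet-specific sizes (256
#' combinations).
#'
#' @return Named list of axis values.
#' @export
commonHyperGrid <- function() {
  list(optimizer = c("adam", "rmsprop", "sgd"),
       learningRate = c(0.0001, 0.001, 0.01),
       batchSize = c(32L, 64L, 128L),
       l2 = c(0.1, 0.2, 0.3),
       dropout = c(0.1, 0.2, 0.3),
       epochs = c(100L, 200L, 300L, 400L, 500L, 1000L))
}

#' @rdname commonHyperGrid
#' @export
lstmHyperGrid <- function() {
  list(units1 = c(32L, 64L, 128L, 256L), units2 = c(32L, 64L, 128L, 256L))
}

#' @rdname commonHyperGrid
#' @export
eegnetHyperGrid <- function() {
  list(LK = c(16L, 32L, 64L, 128L), F1 = c(4L, 6L, 8L, 16L),
       F2 = c(4L, 6L, 8L, 16L), D = c(1L, 2L, 4L, 6L))
}

# Best row: maximize kappa, tie-break by accuracy, then first occurrence.
selectBestRow <- function(log) {
  best <- which(log$kappa == max(log$kappa))
  if (length(best) > 1L)
    best <- best[log$accuracy[best] == max(log$accuracy[best])]
  best[1L]
}

#' Re-select the best configuration from a grid log
#'
#' @param log the `log` data.frame of a [GridResult-class].
#' @return Named list of the winning configuration (without the score
#'   columns).
#' @export
selectBest <- function(log) {
  i <- selectBestRow(log)
  as.list(log[i, setdiff(names(log), c("accuracy", "kappa")), drop = FALSE])
}

#' Exhaustive grid search
#'
#' Enumerates the full Cartesian product of `grid` in deterministic order
#' (first axis fastest), evaluates every configuration once with
#' `evalFn`, and selects the configuration maximizing kappa (ties broken
#' by accuracy, then enumeration order). Stage `"common"` is the shared
#' search with the architecture fixed; stage `"specific"` fixes the best
#' common configuration (passed via `fixed`) and searches the
#' architecture axes.
#'
#' @param evalFn function taking one configuration (named list, the grid
#'   axes plus `fixed`) and returning `list(accuracy =, kappa =)`.
#' @param grid named list of axis values, e.g. [commonHyperGrid()].
#' @param stage `"common"` or `"specific"`.
#' @param fixed named list of settings merged into every configuration.
#' @param verbose print progress every 50 configurations.
#' @return A [GridResult-class]; the log has one row per configuration.
#' @export
gridSearch <- function(evalFn, grid, stage = c("common", "specific"),
                       fixed = list(), verbose = FALSE) {
  stage <- match.arg(stage)
  if (!length(grid) || any(!lengths(grid)))
    stop("gridSearch: empty grid")
  combos <- expand.grid(grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  scores <- matrix(NA_real_, nrow(combos), 2L,
                   dimnames = list(NULL, c("accuracy", "kappa")))
  for (i in seq_len(nrow(combos))) {
    config <- c(as.list(combos[i, , drop = FALSE]), fixed)
    res <- evalFn(config)
    scores[i, ] <- c(res$accuracy, res$kappa)
    if (verbose && i %% 50L == 0L)
      message("gridSearch: ", i, "/", nrow(combos))
  }
  log <- cbind(combos, as.data.frame(scores))
  new("GridResult", log = log, best = c(selectBest(log), fixed),
      stage = stage)
}

#' Build an evaluation function for the grid search
#'
#' Adapts a decoder builder and a train/validation split into the
#' `evalFn` consumed by [gridSearch()]: each configuration is built
#' (architecture axes + `dropout`/`l2`), trained (optimizer axes) and
#' scored on the validation set by accuracy and Cohen's kappa.
#'
#' @param builder function(config) returning a [NeuralDecoder-class];
#'   receives the full configuration.
#' @param x,y training inputs and zero-based labels.
#' @param valX,valY validation inputs and labels.
#' @param seed seed forwarded to training.
#' @return A function usable as `evalFn` in [gridSearch()].
#' @export
decoderEvalFn <- function(builder, x, y, valX, valY, seed = 42L) {
  force(builder); force(x); force(y); force(valX); force(valY)
  function(config) {
    model <- builder(config)
    tc <- trainConfig(optimizer = config$optimizer %||% "adam",
                      learningRate = config$learningRate %||% 1e-3,
                      batchSize = config$batchSize %||% 32L,
                      epochs = config$epochs %||% 100L, seed = seed)
    fit <- trainDecoder(model, x, y, tc)
    pred <- predictClasses(fit, valX)
    list(accuracy = accuracyScore(valY, pred),
         kappa = cohenKappa(valY, pred))
  }
}
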