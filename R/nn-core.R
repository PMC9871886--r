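# Minimal deterministic deep-learning core used by the decoders: dense,
# LSTM, batch normalization, dropout, the EEGNet convolution stack
# (temporal, depthwise-spatial and separable convolutions, ELU, average
# pooling), plus softmax cross-entropy and the Adam / RMSprop / SGD
# update rules. Layers are environments holding parameters, gradients
# and per-batch caches; forward/backward are dispatched on layer$type.
# All matrices are double precision; heavy lifting is BLAS matmuls via
# im2col reshapes.

newLayer <- function(type, ...) {
  env <- new.env(parent = emptyenv())
  env$type <- type
  env$params <- list()
  env$grads <- list()
  env$l2 <- 0
  env$l2Params <- character()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = env)
  env
}

glorot <- function(fanIn, fanOut, dims = c(fanIn, fanOut)) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(runif(prod(dims), -lim, lim), dims)
}

denseLayer <- function(inDim, outDim, l2 = 0) {
  layer <- newLayer("dense", inDim = inDim, outDim = outDim)
  layer$params <- list(W = glorot(inDim, outDim), b = numeric(outDim))
  layer$l2 <- l2
  layer$l2Params <- "W"
  layer
}

# LSTM over (batch, steps, features); gate columns ordered i, f, g, o.
# Forget-gate bias initialized to 1 (standard practice, helps gradient
# flow early in training).
lstmLayer <- function(inDim, units, returnSequences = FALSE, l2 = 0) {
  layer <- newLayer("lstm", inDim = inDim, units = units,
                    returnSequences = returnSequences)
  H <- units
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1
  layer$params <- list(Wx = glorot(inDim, 4 * H, c(inDim, 4 * H)),
                       Wh = glorot(H, 4 * H, c(H, 4 * H)), b = b)
  layer$l2 <- l2
  layer$l2Params <- c("Wx", "Wh")
  layer
}

# Batch normalization over the feature axis of a 2-D (batch, features),
# 3-D (batch, steps, features) or 4-D (batch, maps, ...) input; `mode`
# names which axis carries the features.
batchNormLayer <- function(nFeatures, mode = c("cols", "seq", "maps"),
                           momentum = 0.9, eps = 1e-3) {
  layer <- newLayer("batchnorm", nFeatures = nFeatures,
                    mode = match.arg(mode), momentum = momentum, eps = eps)
  layer$params <- list(gamma = rep(1, nFeatures), beta = numeric(nFeatures))
  layer$runMean <- numeric(nFeatures)
  layer$runVar <- rep(1, nFeatures)
  layer
}

dropoutLayer <- function(rate) newLayer("dropout", rate = rate)

eluLayer <- function() newLayer("elu")

# Temporal convolution: (batch, channels, T) -> (batch, F1, channels, T),
# kernel (1, LK), 'same' padding, linear, no bias (as in EEGNet).
tempConvLayer <- function(lk, f1) {
  layer <- newLayer("tempconv", lk = lk, f1 = f1)
  layer$params <- list(K = glorot(lk, f1, c(lk, f1)))
  layer
}

# Depthwise spatial convolution: (batch, F1, C, T) -> (batch, F1*D, T),
# kernel (C, 1), 'valid', no bias; optional max-norm constraint on each
# spatial kernel.
depthwiseConvLayer <- function(channels, f1, d, maxNorm = 1) {
  layer <- newLayer("depthwise", channels = channels, f1 = f1, d = d,
                    maxNorm = maxNorm)
  layer$params <- list(Wd = glorot(channels, d, c(d, channels, f1)))
  layer
}

# Separable convolution: per-map temporal depthwise (1 x kernel, 'same')
# followed by a pointwise map mix: (batch, M, T) -> (batch, F2, T).
sepConvLayer <- function(nMaps, f2, kernel = 16L) {
  layer <- newLayer("sepconv", nMaps = nMaps, f2 = f2, kernel = kernel)
  layer$params <- list(Kd = glorot(kernel, 1, c(kernel, nMaps)),
                       Wp = glorot(nMaps, f2, c(nMaps, f2)))
  layer
}

avgPoolLayer <- function(k) newLayer("avgpool", k = k)

# (batch, maps, T) -> (batch, T, maps): pooled time becomes the sequence
# axis, maps become per-step features.
toSequenceLayer <- function() newLayer("toseq")

flattenLayer <- function() newLayer("flatten")

samePad <- function(lk) {
  padL <- (lk - 1L) %/% 2L
  c(padL, lk - 1L - padL)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---------------------------------------------------------------------
## forward / backward dispatch

layerForward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    dense = {
      layer$x <- x
      sweep(x %*% layer$params$W, 2L, layer$params$b, `+`)
    },
    lstm = lstmForward(layer, x),
    batchnorm = bnForward(layer, x, training),
    dropout = {
      if (training && layer$rate > 0) {
        layer$mask <- array((runif(length(x)) >= layer$rate) /
                              (1 - layer$rate), dim(x))
        x * layer$mask
      } else {
        layer$mask <- NULL
        x
      }
    },
    elu = {
      y <- ifelse(x > 0, x, exp(pmin(x, 50)) - 1)
      layer$x <- x; layer$y <- y
      y
    },
    tempconv = tempConvForward(layer, x),
    depthwise = depthwiseForward(layer, x),
    sepconv = sepConvForward(layer, x),
    avgpool = avgPoolForward(layer, x),
    toseq = {
      layer$dimIn <- dim(x)
      aperm(x, c(1L, 3L, 2L))
    },
    flatten = {
      layer$dimIn <- dim(x)
      matrix(x, dim(x)[1L], prod(dim(x)[-1L]))
    },
    stop("unknown layer type ", layer$type)
  )
}

layerBackward <- function(layer, d) {
  switch(layer$type,
    dense = {
      layer$grads <- list(W = crossprod(layer$x, d), b = colSums(d))
      d %*% t(layer$params$W)
    },
    lstm = lstmBackward(layer, d),
    batchnorm = bnBackward(layer, d),
    dropout = if (is.null(layer$mask)) d else d * layer$mask,
    elu = d * ifelse(layer$x > 0, 1, layer$y + 1),
    tempconv = tempConvBackward(layer, d),
    depthwise = depthwiseBackward(layer, d),
    sepconv = sepConvBackward(layer, d),
    avgpool = avgPoolBackward(layer, d),
    toseq = aperm(d, c(1L, 3L, 2L)),
    flatten = array(d, layer$dimIn),
    stop("unknown layer type ", layer$type)
  )
}

## ---------------------------------------------------------------------
## LSTM

lstmForward <- function(layer, x) {
  d <- dim(x)
  B <- d[1L]; S <- d[2L]
  H <- layer$units
  Wx <- layer$params$Wx; Wh <- layer$params$Wh; b <- layer$params$b
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- vector("list", S)
  if (layer$returnSequences) out <- array(0, c(B, S, H))
  for (t in seq_len(S)) {
    xt <- matrix(x[, t, ], B, d[3L])
    A <- xt %*% Wx + h %*% Wh
    A <- sweep(A, 2L, b, `+`)
    i <- sigmoid(A[, 1:H, drop = FALSE])
    f <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(A[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(A[, (3 * H + 1):(4 * H), drop = FALSE])
    cPrev <- cc
    cc <- f * cPrev + i * g
    tc <- tanh(cc)
    hPrev <- h
    h <- o * tc
    cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o, cPrev = cPrev,
                       tc = tc, hPrev = hPrev)
    if (layer$returnSequences) out[, t, ] <- h
  }
  layer$cache <- cache
  layer$dims <- d
  if (layer$returnSequences) out else h
}

lstmBackward <- function(layer, d) {
  dims <- layer$dims
  B <- dims[1L]; S <- dims[2L]; Din <- dims[3L]
  H <- layer$units
  Wx <- layer$params$Wx; Wh <- layer$params$Wh
  dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- numeric(4 * H)
  dX <- array(0, dims)
  dhNext <- matrix(0, B, H); dcNext <- matrix(0, B, H)
  for (t in rev(seq_len(S))) {
    cc <- layer$cache[[t]]
    dh <- dhNext
    if (layer$returnSequences) dh <- dh + matrix(d[, t, ], B, H)
    else if (t == S) dh <- dh + d
    dc <- dcNext + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g * cc$i * (1 - cc$i)
    df <- dc * cc$cPrev * cc$f * (1 - cc$f)
    dg <- dc * cc$i * (1 - cc$g^2)
    do_ <- dh * cc$tc * cc$o * (1 - cc$o)
    dA <- cbind(di, df, dg, do_)
    dWx <- dWx + crossprod(cc$xt, dA)
    dWh <- dWh + crossprod(cc$hPrev, dA)
    db <- db + colSums(dA)
    dX[, t, ] <- dA %*% t(Wx)
    dhNext <- dA %*% t(Wh)
    dcNext <- dc * cc$f
  }
  layer$grads <- list(Wx = dWx, Wh = dWh, b = db)
  dX
}

## ---------------------------------------------------------------------
## batch normalization

# Reshape any supported input to an N x features matrix (features in
# columns) and remember how to undo it.
bnToMatrix <- function(layer, x) {
  layer$dimIn <- dim(x)
  switch(layer$mode,
    cols = x,
    seq = matrix(x, prod(dim(x)[1:2]), dim(x)[3L]),
    maps = {
      p <- c(1L, seq_along(dim(x))[-(1:2)], 2L)  # feature maps last
      matrix(aperm(x, p), prod(dim(x)[-2L]), dim(x)[2L])
    })
}

bnFromMatrix <- function(layer, m) {
  d <- layer$dimIn
  switch(layer$mode,
    cols = m,
    seq = array(m, d),
    maps = {
      k <- length(d)
      aperm(array(m, c(d[1L], d[-(1:2)], d[2L])),
            c(1L, k, seq_len(k - 2L) + 1L))
    })
}

bnForward <- function(layer, x, training) {
  m <- bnToMatrix(layer, x)
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2L, mu)
    v <- colMeans(xc^2)
    layer$runMean <- layer$momentum * layer$runMean + (1 - layer$momentum) * mu
    layer$runVar <- layer$momentum * layer$runVar + (1 - layer$momentum) * v
    istd <- 1 / sqrt(v + layer$eps)
    xhat <- sweep(xc, 2L, istd, `*`)
    layer$xhat <- xhat; layer$istd <- istd
    out <- sweep(sweep(xhat, 2L, layer$params$gamma, `*`), 2L,
                 layer$params$beta, `+`)
  } else {
    istd <- 1 / sqrt(layer$runVar + layer$eps)
    xhat <- sweep(sweep(m, 2L, layer$runMean), 2L, istd, `*`)
    out <- sweep(sweep(xhat, 2L, layer$params$gamma, `*`), 2L,
                 layer$params$beta, `+`)
  }
  bnFromMatrix(layer, out)
}

bnBackward <- function(layer, d) {
  dm <- bnToMatrix(layer, d)
  n <- nrow(dm)
  xhat <- layer$xhat
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2L, layer$params$gamma, `*`)
  dx <- sweep(dxhat, 2L, colMeans(dxhat)) -
    xhat * matrix(colMeans(dxhat * xhat), n, ncol(dm), byrow = TRUE)
  dx <- sweep(dx, 2L, layer$istd, `*`)
  layer$grads <- list(gamma = dgamma, beta = dbeta)
  bnFromMatrix(layer, dx)
}

## ---------------------------------------------------------------------
## EEGNet convolutions

tempConvForward <- function(layer, x) {
  d <- dim(x)                      # (B, C, T)
  B <- d[1L]; C <- d[2L]; Tn <- d[3L]
  lk <- layer$lk
  pad <- samePad(lk)
  M <- matrix(x, B * C, Tn)
  Xp <- cbind(matrix(0, B * C, pad[1L]), M, matrix(0, B * C, pad[2L]))
  Xcol <- matrix(0, B * C * Tn, lk)
  for (k in seq_len(lk))
    Xcol[, k] <- as.vector(Xp[, k:(k + Tn - 1L)])
  Y <- Xcol %*% layer$params$K     # (B*C*T, F1)
  layer$Xcol <- Xcol
  layer$dimIn <- d
  aperm(array(Y, c(B, C, Tn, layer$f1)), c(1L, 4L, 2L, 3L))
}

tempConvBackward <- function(layer, d) {
  din <- layer$dimIn
  B <- din[1L]; C <- din[2L]; Tn <- din[3L]
  lk <- layer$lk
  pad <- samePad(lk)
  dY <- matrix(aperm(d, c(1L, 3L, 4L, 2L)), B * C * Tn, layer$f1)
  layer$grads <- list(K = crossprod(layer$Xcol, dY))
  dXcol <- dY %*% t(layer$params$K)
  dXp <- matrix(0, B * C, Tn + lk - 1L)
  for (k in seq_len(lk))
    dXp[, k:(k + Tn - 1L)] <- dXp[, k:(k + Tn - 1L)] +
      matrix(dXcol[, k], B * C, Tn)
  array(dXp[, (pad[1L] + 1L):(pad[1L] + Tn)], din)
}

depthwiseForward <- function(layer, x) {
  d <- dim(x)                      # (B, F1, C, T)
  B <- d[1L]; F1 <- d[2L]; C <- d[3L]; Tn <- d[4L]
  D <- layer$d
  y <- array(0, c(B, F1 * D, Tn))
  layer$mats <- vector("list", F1)
  for (f in seq_len(F1)) {
    Mf <- matrix(aperm(array(x[, f, , ], c(B, C, Tn)), c(2L, 1L, 3L)),
                 C, B * Tn)
    layer$mats[[f]] <- Mf
    Yf <- matrix(layer$params$Wd[, , f], D, C) %*% Mf   # (D, B*T)
    y[, (f - 1L) * D + seq_len(D), ] <-
      aperm(array(Yf, c(D, B, Tn)), c(2L, 1L, 3L))
  }
  layer$dimIn <- d
  y
}

depthwiseBackward <- function(layer, d) {
  din <- layer$dimIn
  B <- din[1L]; F1 <- din[2L]; C <- din[3L]; Tn <- din[4L]
  D <- layer$d
  dWd <- array(0, dim(layer$params$Wd))
  dx <- array(0, din)
  for (f in seq_len(F1)) {
    dYf <- matrix(aperm(array(d[, (f - 1L) * D + seq_len(D), ],
                              c(B, D, Tn)), c(2L, 1L, 3L)), D, B * Tn)
    dWd[, , f] <- tcrossprod(dYf, layer$mats[[f]])
    dMf <- t(matrix(layer$params$Wd[, , f], D, C)) %*% dYf   # (C, B*T)
    dx[, f, , ] <- aperm(array(dMf, c(C, B, Tn)), c(2L, 1L, 3L))
  }
  layer$grads <- list(Wd = dWd)
  dx
}

sepConvForward <- function(layer, x) {
  d <- dim(x)                      # (B, M, T)
  B <- d[1L]; M <- d[2L]; Tn <- d[3L]
  kk <- layer$kernel
  pad <- samePad(kk)
  y1 <- array(0, d)
  layer$Xp <- vector("list", M)
  for (m in seq_len(M)) {
    Xm <- matrix(x[, m, ], B, Tn)
    Xp <- cbind(matrix(0, B, pad[1L]), Xm, matrix(0, B, pad[2L]))
    layer$Xp[[m]] <- Xp
    acc <- matrix(0, B, Tn)
    for (k in seq_len(kk))
      acc <- acc + layer$params$Kd[k, m] * Xp[, k:(k + Tn - 1L)]
    y1[, m, ] <- acc
  }
  P <- matrix(aperm(y1, c(1L, 3L, 2L)), B * Tn, M)
  layer$P <- P
  layer$dimIn <- d
  aperm(array(P %*% layer$params$Wp, c(B, Tn, layer$f2)), c(1L, 3L, 2L))
}

sepConvBackward <- function(layer, d) {
  din <- layer$dimIn
  B <- din[1L]; M <- din[2L]; Tn <- din[3L]
  kk <- layer$kernel
  pad <- samePad(kk)
  dY2 <- matrix(aperm(d, c(1L, 3L, 2L)), B * Tn, layer$f2)
  dWp <- crossprod(layer$P, dY2)
  dP <- dY2 %*% t(layer$params$Wp)                 # (B*T, M)
  dy1 <- aperm(array(dP, c(B, Tn, M)), c(1L, 3L, 2L))
  dKd <- array(0, dim(layer$params$Kd))
  dx <- array(0, din)
  for (m in seq_len(M)) {
    dm <- matrix(dy1[, m, ], B, Tn)
    Xp <- layer$Xp[[m]]
    dXp <- matrix(0, B, Tn + kk - 1L)
    for (k in seq_len(kk)) {
      dKd[k, m] <- sum(Xp[, k:(k + Tn - 1L)] * dm)
      dXp[, k:(k + Tn - 1L)] <- dXp[, k:(k + Tn - 1L)] +
        layer$params$Kd[k, m] * dm
    }
    dx[, m, ] <- dXp[, (pad[1L] + 1L):(pad[1L] + Tn)]
  }
  layer$grads <- list(Kd = dKd, Wp = dWp)
  dx
}

avgPoolForward <- function(layer, x) {
  d <- dim(x)                      # (B, M, T)
  k <- layer$k
  Tout <- d[3L] %/% k
  layer$dimIn <- d
  layer$tOut <- Tout
  y <- array(0, c(d[1L], d[2L], Tout))
  for (j in seq_len(k))
    y <- y + x[, , seq(j, by = k, length.out = Tout), drop = FALSE]
  y / k
}

avgPoolBackward <- function(layer, d) {
  din <- layer$dimIn
  k <- layer$k
  dx <- array(0, din)
  for (j in seq_len(k))
    dx[, , seq(j, by = k, length.out = layer$tOut)] <- d / k
  dx
}

## ---------------------------------------------------------------------
## softmax / loss / optimizers

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# L2 penalty of a network (sum over flagged parameters of l2 * sum(w^2)).
l2Penalty <- function(layers) {
  s <- 0
  for (layer in layers)
    for (nm in layer$l2Params)
      s <- s + layer$l2 * sum(layer$params[[nm]]^2)
  s
}

addL2Grads <- function(layers) {
  for (layer in layers)
    for (nm in layer$l2Params)
      layer$grads[[nm]] <- layer$grads[[nm]] + 2 * layer$l2 * layer$params[[nm]]
  invisible(NULL)
}

makeOptimizer <- function(name = c("adam", "rmsprop", "sgd"), lr) {
  name <- match.arg(tolower(name), c("adam", "rmsprop", "sgd"))
  env <- new.env(parent = emptyenv())
  env$name <- name
  env$lr <- lr
  env$t <- 0L
  env$state <- list()
  env
}

optimizerStep <- function(opt, layers) {
  opt$t <- opt$t + 1L
  for (li in seq_along(layers)) {
    layer <- layers[[li]]
    if (!length(layer$grads)) next
    for (nm in names(layer$grads)) {
      key <- paste0(li, ".", nm)
      g <- layer$grads[[nm]]
      w <- layer$params[[nm]]
      if (opt$name == "sgd") {
        w <- w - opt$lr * g
      } else if (opt$name == "rmsprop") {
        s <- opt$state[[key]]
        if (is.null(s)) s <- array(0, dim(g) %||% length(g))
        s <- 0.9 * s + 0.1 * g^2
        opt$state[[key]] <- s
        w <- w - opt$lr * g / (sqrt(s) + 1e-7)
      } else {                      # adam
        s <- opt$state[[key]]
        if (is.null(s)) s <- list(m = 0 * g, v = 0 * g)
        s$m <- 0.9 * s$m + 0.1 * g
        s$v <- 0.999 * s$v + 0.001 * g^2
        opt$state[[key]] <- s
        mh <- s$m / (1 - 0.9^opt$t)
        vh <- s$v / (1 - 0.999^opt$t)
        w <- w - opt$lr * mh / (sqrt(vh) + 1e-7)
      }
      layer$params[[nm]] <- w
    }
    if (layer$type == "depthwise" && is.finite(layer$maxNorm)) {
      Wd <- layer$params$Wd          # (D, C, F1): constrain over C
      for (f in seq_len(dim(Wd)[3L])) {
        for (dd in seq_len(dim(Wd)[1L])) {
          nrm <- sqrt(sum(Wd[dd, , f]^2))
          if (nrm > layer$maxNorm)
            Wd[dd, , f] <- Wd[dd, , f] * layer$maxNorm / nrm
        }
      }
      layer$params$Wd <- Wd
    }
    layer$grads <- list()
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deep-copy a list of layer environments (weights and config, not caches).
cloneLayers <- function(layers) {
  lapply(layers, function(layer) {
    env <- new.env(parent = emptyenv())
    for (nm in ls(layer, all.names = TRUE)) {
      if (nm %in% c("cache", "mats", "Xcol", "Xp", "P", "x", "y", "xhat",
                    "mask"))
        next
      assign(nm, get(nm, envir = layer), envir = env)
    }
    env
  })
}
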