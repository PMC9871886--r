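# Reference LSTM cell in the textbook parameterization: each gate has a
# single weight matrix over the concatenated vector [h_{t-1}, x_t]. This
# form is kept deliberately independent of the batched sequence layer in
# nn-core.R (separate input/recurrent matrices, fused gate matmuls); the
# two are checked against each other in the test suite.

#' Reference LSTM cell parameters
#'
#' Gate weight matrices act on the concatenation `[h, x]` (hidden state
#' first), so each has shape `hidden x (hidden + input)`.
#'
#' @param wF,wI,wC,wO forget / input / candidate / output gate weights.
#' @param bF,bI,bC,bO gate biases (length `hidden`).
#' @return A list of class `"LSTMCellParams"`.
#' @export
lstmCellParams <- function(wF, wI, wC, wO, bF, bI, bC, bO) {
  mats <- list(wF = wF, wI = wI, wC = wC, wO = wO)
  shp <- dim(mats[[1L]])
  for (m in mats)
    if (!identical(dim(m), shp))
      stop("lstmCellParams: all gate matrices must share one shape")
  H <- shp[1L]
  for (b in list(bF, bI, bC, bO))
    if (length(b) != H)
      stop("lstmCellParams: biases must have length ", H)
  structure(list(wF = wF, wI = wI, wC = wC, wO = wO, bF = bF, bI = bI,
                 bC = bC, bO = bO, hidden = H, input = shp[2L] - H),
            class = "LSTMCellParams")
}

#' One reference LSTM cell step
#'
#' Computes the standard cell update: sigmoid forget, input and output
#' gates over `[h, x]`, a tanh candidate, `c' = f * c + i * cTilde` and
#' `h' = o * tanh(c')`.
#'
#' @param x input vector at this step.
#' @param state list with `h` (previous output) and `c` (cell state).
#' @param params an [lstmCellParams()] object.
#' @return List with updated `h` and `c`.
#' @examples
#' p <- lstmCellParams(matrix(0, 1, 2), matrix(0, 1, 2), matrix(0, 1, 2),
#'                     matrix(0, 1, 2), 0, 0, 0, 0)
#' lstmCellStep(0, list(h = 0, c = 1), p)  # h' = 0.5 * tanh(0.5)
#' @export
lstmCellStep <- function(x, state, params) {
  hx <- c(state$h, x)
  if (length(hx) != params$hidden + params$input)
    stop("lstmCellStep: [h, x] has length ", length(hx), ", expected ",
         params$hidden + params$input)
  f <- sigmoid(as.vector(params$wF %*% hx) + params$bF)
  i <- sigmoid(as.vector(params$wI %*% hx) + params$bI)
  cTilde <- tanh(as.vector(params$wC %*% hx) + params$bC)
  cNew <- f * state$c + i * cTilde
  o <- sigmoid(as.vector(params$wO %*% hx) + params$bO)
  list(h = o * tanh(cNew), c = cNew)
}

#' Run the reference cell over a sequence
#'
#' @param x `steps x features` matrix.
#' @param params an [lstmCellParams()] object.
#' @param h0,c0 initial state (defaults to zeros).
#' @return `steps x hidden` matrix of hidden outputs.
#' @export
lstmCellSequence <- function(x, params, h0 = NULL, c0 = NULL) {
  H <- params$hidden
  state <- list(h = h0 %||% numeric(H), c = c0 %||% numeric(H))
  out <- matrix(0, nrow(x), H)
  for (t in seq_len(nrow(x))) {
    state <- lstmCellStep(x[t, ], state, params)
    out[t, ] <- state$h
  }
  out
}

# Convert a batched lstmLayer's weights (Wx: D x 4H, Wh: H x 4H, gate
# order i,f,g,o) to the concatenated reference parameterization.
layerWeightsToCellParams <- function(Wx, Wh, b) {
  H <- ncol(Wh) / 4L
  gate <- function(k) {
    cols <- ((k - 1L) * H + 1L):(k * H)
    list(w = t(rbind(Wh[, cols, drop = FALSE], Wx[, cols, drop = FALSE])),
         b = b[cols])
  }
  gi <- gate(1L); gf <- gate(2L); gc <- gate(3L); go <- gate(4L)
  lstmCellParams(gf$w, gi$w, gc$w, go$w, gf$b, gi$b, gc$b, go$b)
}
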