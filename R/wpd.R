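# Wavelet packet decomposition: recursive filter-and-downsample of both
# the approximation and the detail branch, giving 2^L equal-width
# frequency bands at level L. Periodized orthonormal filtering, so the
# transform conserves energy (Parseval) on even-length signals.

.dbFilters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314469025, 0.836516303737469, 0.22414386804185735,
          -0.12940952255092145),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.02798376941685986, -0.18703481171909309, 0.03084138183556076,
          0.0328830116668852, -0.01059740178506903)
)

#' Orthogonal wavelet analysis filter pair
#'
#' Returns the low-pass (`g`) and high-pass (`h`) analysis taps of a
#' Daubechies wavelet as a quadrature-mirror pair:
#' `h[k] = (-1)^(k+1) g[L - 1 - k]` (zero-based). The taps are
#' orthonormal (sum of squares one), so the packet transform built from
#' them conserves energy.
#'
#' @param name `"db1"` (Haar), `"db2"` or `"db4"` (the package default
#'   for EEG work, 8 taps).
#' @return A list of class `"WaveletFilters"` with elements `g`, `h`,
#'   `name`.
#' @export
waveletFilters <- function(name = "db4") {
  rec <- .dbFilters[[name]]
  if (is.null(rec))
    stop("waveletFilters: unknown wavelet '", name, "' (available: ",
         paste(names(.dbFilters), collapse = ", "), ")")
  L <- length(rec)
  g <- rev(rec)                              # analysis low-pass
  h <- (-1)^seq_len(L) * rec                 # analysis high-pass (QMF)
  structure(list(g = g, h = h, name = name), class = "WaveletFilters")
}

# One periodized analysis step: correlate with the reversed filter at
# even positions (offset L/2 - 1, matching the usual periodization
# convention) and keep every second sample. Odd-length inputs are
# extended by repeating the final sample.
analysisStep <- function(x, filt) {
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  N <- length(x)
  L <- length(filt)
  idx <- outer(2L * (seq_len(N %/% 2L) - 1L), seq_len(L) - 1L, `+`)
  idx <- (idx - (L %/% 2L - 1L)) %% N + 1L
  as.vector(matrix(x[idx], ncol = L) %*% rev(filt))
}

#' Wavelet packet decomposition of a signal
#'
#' Builds the full packet tree down to `level`: the root node is the
#' input signal; each node's low-pass child (index `2j`) and high-pass
#' child (index `2j + 1`, zero-based natural order) are produced by
#' filtering and downsampling.
#'
#' @param signal numeric vector.
#' @param filters a [waveletFilters()] pair.
#' @param level decomposition depth (>= 0).
#' @return A [WPDTree-class].
#' @examples
#' tree <- wpdDecompose(sin(2 * pi * 10 * (0:255) / 128), level = 4)
#' tree
#' @export
wpdDecompose <- function(signal, filters = waveletFilters("db4"),
                         level = 4L) {
  level <- as.integer(level)
  if (level < 0L) stop("wpdDecompose: level must be >= 0")
  if (length(signal) < length(filters$g))
    stop("wpdDecompose: signal shorter than the filter support (",
         length(filters$g), " taps)")
  coeffs <- vector("list", level + 1L)
  coeffs[[1L]] <- list(as.numeric(signal))
  if (level > 0L) {
    for (i in seq_len(level)) {
      parents <- coeffs[[i]]
      kids <- vector("list", 2L * length(parents))
      for (j in seq_along(parents)) {
        kids[[2L * j - 1L]] <- analysisStep(parents[[j]], filters$g)
        kids[[2L * j]] <- analysisStep(parents[[j]], filters$h)
      }
      coeffs[[i + 1L]] <- kids
    }
  }
  new("WPDTree", coeffs = coeffs, level = level, wavelet = filters$name)
}

#' Extract one node's coefficients
#'
#' @param tree a [WPDTree-class].
#' @param level tree level (0 = root).
#' @param node zero-based node index in natural order.
#' @return Numeric coefficient vector.
#' @export
wpdNode <- function(tree, level, node) {
  if (level < 0L || level > tree@level)
    stop("wpdNode: level out of range")
  if (node < 0L || node >= 2L^level)
    stop("wpdNode: node out of range for level ", level)
  tree@coeffs[[level + 1L]][[node + 1L]]
}

# Natural-order indices (zero-based) of the level-L nodes sorted by
# ascending band center. Because each downsampling stage mirrors the
# spectrum of the high-pass branch, the ordering is the binary-reflected
# Gray code: at an even frequency position the children appear (low,
# high), at an odd one (high, low).
frequencyOrder <- function(level) {
  ord <- 0L
  if (level > 0L) {
    for (i in seq_len(level)) {
      ord <- unlist(lapply(seq_along(ord), function(p) {
        n <- ord[p]
        if (p %% 2L == 1L) c(2L * n, 2L * n + 1L)
        else c(2L * n + 1L, 2L * n)
      }))
    }
  }
  ord
}

#' Leaf coefficients of a packet tree
#'
#' @param tree a [WPDTree-class].
#' @param order `"frequency"` (ascending band center; the sequence axis
#'   used by the LSTM decoder) or `"natural"` (filter recursion order).
#' @return List of `2^level` coefficient vectors.
#' @export
wpdLeaves <- function(tree, order = c("frequency", "natural")) {
  order <- match.arg(order)
  leaves <- tree@coeffs[[tree@level + 1L]]
  if (order == "frequency") leaves[frequencyOrder(tree@level) + 1L]
  else leaves
}
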