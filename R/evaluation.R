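# Evaluation statistics: accuracy, Cohen's kappa, the pinned paired
# Wilcoxon signed-rank variant, and method-comparison tables.

#' Classification accuracy
#'
#' @param yTrue,yPred equal-length label vectors.
#' @return Fraction of matching entries.
#' @export
accuracyScore <- function(yTrue, yPred) {
  if (!length(yTrue) || length(yTrue) != length(yPred))
    stop("accuracyScore: inputs must be non-empty and of equal length")
  mean(yTrue == yPred)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where the
#' expected agreement `p_e` comes from the product of the marginal label
#' distributions. The multiclass form used as the standard metric of the
#' BCI competitions.
#'
#' @param yTrue,yPred equal-length label vectors.
#' @param nClasses number of classes; defaults to the classes observed.
#' @return Kappa in `[-1, 1]`. When both sides are constant and
#'   identical (`p_e = 1`) the agreement is perfect by convention and 1
#'   is returned; constant but different inputs are an error.
#' @export
cohenKappa <- function(yTrue, yPred, nClasses = NULL) {
  if (!length(yTrue) || length(yTrue) != length(yPred))
    stop("cohenKappa: inputs must be non-empty and of equal length")
  lev <- if (is.null(nClasses)) sort(unique(c(yTrue, yPred)))
         else seq_len(nClasses) - 1L
  if (!all(c(yTrue, yPred) %in% lev))
    stop("cohenKappa: labels outside 0..", max(lev))
  cm <- table(factor(yTrue, levels = lev), factor(yPred, levels = lev))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1 - 1e-15) {
    if (po >= 1 - 1e-15) return(1)
    stop("cohenKappa: degenerate marginals (both raters constant but ",
         "unequal)")
  }
  (po - pe) / (1 - pe)
}

#' Paired Wilcoxon signed-rank test (pinned variant)
#'
#' The variant used throughout the package's method comparisons:
#' zero differences are discarded, `|d|` is ranked with midranks for
#' ties, `W+` is the positive-rank sum, and
#' `Z = (W+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48)`
#' (tie-corrected variance, no continuity correction) with a two-sided
#' normal p-value. `|d|` values are rounded to `digits` decimals before
#' ranking so that ties between decimal scores are detected despite
#' binary floating-point representation. An exact two-sided p-value by
#' enumeration of all `2^n` sign assignments is available for small `n`.
#'
#' @param a,b equal-length paired vectors (e.g. per-subject kappas of two
#'   methods).
#' @param exact also compute the exact enumeration p-value (requires
#'   `n <= 20` after zero removal).
#' @param digits decimal rounding applied to `|d|` before ranking.
#' @return A [WilcoxonResult-class]; with `exact = TRUE` the exact
#'   p-value is attached as attribute `"pExact"`.
#' @export
wilcoxonSignedRank <- function(a, b, exact = FALSE, digits = 10L) {
  if (length(a) != length(b))
    stop("wilcoxonSignedRank: paired vectors must have equal length")
  d <- round(a - b, digits)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("wilcoxonSignedRank: no variation (all differences zero)")
  if (n < 5L)
    warning("wilcoxonSignedRank: fewer than 5 non-zero pairs; the normal ",
            "approximation is unreliable")
  r <- rank(abs(d))               # midranks for ties
  wPlus <- sum(r[d > 0])
  ties <- table(r)
  tcorr <- sum(ties^3 - ties) / 48
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tcorr)
  if (sigma == 0)
    stop("wilcoxonSignedRank: zero variance (all |d| tied at one rank)")
  z <- (wPlus - n * (n + 1) / 4) / sigma
  p <- 2 * stats::pnorm(-abs(z))
  res <- new("WilcoxonResult", z = z, p = p, nEffective = n, wPlus = wPlus)
  if (exact) {
    if (n > 20L) stop("wilcoxonSignedRank: exact mode supports n <= 20")
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wAll <- as.vector(signs %*% r)
    center <- n * (n + 1) / 4
    pExact <- mean(abs(wAll - center) >= abs(wPlus - center) - 1e-12)
    attr(res, "pExact") <- pExact
  }
  res
}

#' Mean and sample standard deviation of one method's scores
#'
#' @param scores a [ScoreTable-class].
#' @param method method (row) name.
#' @return Named numeric vector `c(mean =, sd =)`; the SD uses the n - 1
#'   denominator.
#' @export
summarizeScores <- function(scores, method) {
  stopifnot(is(scores, "ScoreTable"))
  if (!method %in% rownames(scores@values))
    stop("summarizeScores: unknown method '", method, "'")
  v <- scores@values[method, ]
  c(mean = mean(v), sd = stats::sd(v))
}

#' Compare every method against a reference by paired Wilcoxon test
#'
#' For each non-reference method the mean kappa difference
#' (reference - method) and the pinned Wilcoxon signed-rank Z and
#' p-value over the paired per-subject scores are reported.
#'
#' @param scores a [ScoreTable-class].
#' @param reference reference method (row) name.
#' @return data.frame with columns `method`, `meanDiff`, `z`, `p`,
#'   `nEffective`.
#' @export
compareMethods <- function(scores, reference) {
  stopifnot(is(scores, "ScoreTable"))
  v <- scores@values
  if (!reference %in% rownames(v))
    stop("compareMethods: unknown reference '", reference, "'")
  others <- setdiff(rownames(v), reference)
  if (!length(others))
    stop("compareMethods: need at least two methods")
  rows <- lapply(others, function(m) {
    w <- wilcoxonSignedRank(v[reference, ], v[m, ])
    data.frame(method = m, meanDiff = mean(v[reference, ]) - mean(v[m, ]),
               z = w@z, p = w@p, nEffective = w@nEffective)
  })
  do.call(rbind, rows)
}

#' Accuracy and kappa of a trained decoder on a test set
#'
#' Predictions are the argmax of the softmax outputs.
#'
#' @param model a [TrainedDecoder-class] or [NeuralDecoder-class].
#' @param x test inputs matching the decoder kind.
#' @param labels zero-based true labels.
#' @return List with `accuracy` and `kappa`.
#' @export
evaluateDecoder <- function(model, x, labels) {
  nc <- if (is(model, "TrainedDecoder")) model@model@nClasses
        else model@nClasses
  if (any(labels < 0L | labels >= nc))
    stop("evaluateDecoder: labels exceed the decoder's class count")
  pred <- predictClasses(model, x)
  list(accuracy = accuracyScore(labels, pred),
       kappa = cohenKappa(labels, pred, nClasses = nc))
}

#' Read / write a score table as CSV
#'
#' The CSV layout is one row per method: a `method` column followed by
#' one column per subject.
#'
#' @param path CSV file path.
#' @param scores a [ScoreTable-class].
#' @return `readScoreTable` returns a [ScoreTable-class];
#'   `writeScoreTable` returns `path` invisibly.
#' @export
readScoreTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  scoreTable(df)
}

#' @rdname readScoreTable
#' @export
writeScoreTable <- function(scores, path) {
  stopifnot(is(scores, "ScoreTable"))
  df <- data.frame(method = rownames(scores@values), scores@values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Published per-subject kappa scores on BCI Competition IV data set 2a
#'
#' The bundled per-subject kappa values (subjects 1, 2, 3, 5, 6, 7, 8, 9;
#' subject 4 is excluded for corrupted EOG recordings) of the two
#' decoders implemented here and four published competitors, as reported
#' in the motor-imagery decoding literature. These printed scores are the
#' input to the summary statistics and Wilcoxon comparisons.
#'
#' @return A [ScoreTable-class] with six methods and eight subjects.
#' @export
kappaComparisonTable <- function() {
  path <- system.file("extdata", "table7_kappa.csv", package = "midecoder",
                      mustWork = TRUE)
  readScoreTable(path)
}
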