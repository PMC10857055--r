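# Device-agreement statistics: IBI error metrics and Bland-Altman limits,
# classifier metrics, McNemar's test, word error rate, paired t.

#' IBI agreement report (mean error, MAPE, Bland-Altman limits)
#'
#' @param ref Reference interval series (ms), paired 1:1 with `test`.
#' @param test Test interval series (ms).
#' @return List of class `agreementReport`: `n`, `meanError` (ref - test),
#'   `absMeanError`, `mape` (%), `loaLow`, `loaHigh` (bias -/+ 1.96 SD of
#'   the differences).
#' @export
ibiAgreement <- function(ref, test) {
  stopifnot(length(ref) == length(test))
  if (any(ref == 0)) stop("zero-valued reference interval")
  d <- ref - test
  bias <- mean(d)
  s <- stats::sd(d)
  if (is.na(s)) s <- 0
  structure(list(n = length(d), meanError = bias,
                 absMeanError = mean(abs(d)),
                 mape = mean(abs(d) / ref) * 100,
                 loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s),
            class = "agreementReport")
}

#' @export
print.agreementReport <- function(x, ...) {
  cat(sprintf(paste0("Agreement over %d pairs: mean error %.2f ms, ",
                     "absolute %.2f ms, MAPE %.2f%%, LoA [%.2f, %.2f] ms\n"),
              x$n, x$meanError, x$absMeanError, x$mape, x$loaLow, x$loaHigh))
  invisible(x)
}

#' Accuracy, weighted F1 and Cohen's kappa from a confusion matrix
#'
#' Rows are ground truth, columns predictions. Accuracy is the trace over
#' the total; F1 is the per-class harmonic mean of precision and recall,
#' averaged with true-class frequency weights; kappa is
#' `(p_o - p_e) / (1 - p_e)` with expected agreement from the marginal
#' products.
#'
#' @param cm Square numeric matrix of counts (rows = truth).
#' @return Named vector `accuracy`, `weightedF1`, `kappa`.
#' @export
classifierMetrics <- function(cm) {
  cm <- as.matrix(unclass(cm))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  acc <- sum(diag(cm)) / total
  rowS <- rowSums(cm); colS <- colSums(cm)
  prec <- ifelse(colS > 0, diag(cm) / colS, 0)
  rec <- ifelse(rowS > 0, diag(cm) / rowS, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wF1 <- sum(f1 * rowS) / total
  pe <- sum(rowS * colS) / total^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 1
  c(accuracy = acc, weightedF1 = wF1, kappa = kappa)
}

#' McNemar's test on paired classifier outcomes
#'
#' `b` and `c` are the discordant counts of the 2x2 correct/incorrect table
#' (only-A-correct and only-B-correct); the concordant cells are ignored by
#' the test. The default is the uncorrected chi-square
#' `(b - c)^2 / (b + c)`; the continuity-corrected form and the exact
#' two-sided binomial test are available.
#'
#' @param b,c Discordant counts. Alternatively pass a 2x2 matrix as `b`
#'   (cells a, b / c, d, rows = device A correct/incorrect).
#' @param method `"chi2"` (default), `"chi2_corrected"`, or `"exact"`.
#' @return List with `statistic` (chi-square; `NA` for exact), `p`,
#'   `method`, `b`, `c`.
#' @export
mcnemarTest <- function(b, c = NULL,
                        method = c("chi2", "chi2_corrected", "exact")) {
  method <- match.arg(method)
  if (is.matrix(b)) {
    stopifnot(all(dim(b) == 2))
    cc <- b[2, 1]; b <- b[1, 2]
  } else cc <- c
  stopifnot(b >= 0, cc >= 0)
  if (b + cc == 0)
    return(list(statistic = 0, p = 1, method = method, b = b, c = cc))
  if (method == "exact") {
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    return(list(statistic = NA_real_, p = p, method = method, b = b, c = cc))
  }
  stat <- if (method == "chi2") (b - cc)^2 / (b + cc)
          else (abs(b - cc) - 1)^2 / (b + cc)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       method = method, b = b, c = cc)
}

#' Tokenize a transcript for WER scoring
#'
#' Lowercases, strips punctuation, splits on whitespace.
#'
#' @param text Character scalar.
#' @return Character vector of word tokens.
#' @export
tokenizeTranscript <- function(text) {
  x <- tolower(text)
  x <- gsub("[^a-z0-9' ]+", " ", x)
  x <- gsub("(^| )'+|'+( |$)", " ", x)
  tok <- strsplit(trimws(gsub(" +", " ", x)), " ", fixed = TRUE)[[1]]
  tok[nzchar(tok)]
}

#' Word error rate by Levenshtein alignment
#'
#' Unit-cost word-level edit distance with a backtrace splitting the errors
#' into substitutions, deletions (reference words missed) and insertions.
#' `WER = (S + D + I) / N` with `N` the reference length.
#'
#' @param reference Reference transcript (string) or token vector.
#' @param hypothesis Hypothesis transcript (string) or token vector.
#' @param tokenize Apply [tokenizeTranscript()] to string inputs
#'   (default `TRUE`).
#' @return List with `wer`, `S`, `D`, `I`, `N`.
#' @export
wordErrorRate <- function(reference, hypothesis, tokenize = TRUE) {
  ref <- if (tokenize && length(reference) == 1) tokenizeTranscript(reference)
         else as.character(reference)
  hyp <- if (tokenize && length(hypothesis) == 1 && is.character(hypothesis))
           tokenizeTranscript(hypothesis) else as.character(hypothesis)
  n <- length(ref); m <- length(hyp)
  if (!n) stop("empty reference")
  # dp cost matrix and move matrix (1 diag-ok, 2 sub, 3 del, 4 ins)
  D <- matrix(0L, n + 1, m + 1)
  M <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n; M[, 1] <- 3L
  D[1, ] <- 0:m; M[1, ] <- 4L
  M[1, 1] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      same <- ref[i] == hyp[j]
      cSub <- D[i, j] + !same
      cDel <- D[i, j + 1] + 1L
      cIns <- D[i + 1, j] + 1L
      best <- min(cSub, cDel, cIns)
      D[i + 1, j + 1] <- best
      M[i + 1, j + 1] <- if (best == cSub) (if (same) 1L else 2L)
                         else if (best == cDel) 3L else 4L
    }
  }
  S <- Dl <- I <- 0L
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- M[i, j]
    if (mv <= 2L) { S <- S + (mv == 2L); i <- i - 1L; j <- j - 1L }
    else if (mv == 3L) { Dl <- Dl + 1L; i <- i - 1L }
    else { I <- I + 1L; j <- j - 1L }
  }
  list(wer = (S + Dl + I) / n, S = as.integer(S), D = as.integer(Dl),
       I = as.integer(I), N = n)
}

#' Relative improvement between two error rates
#'
#' `(baseline - improved) / baseline * 100`, e.g. for comparing word error
#' rates with and without a language model.
#'
#' @param baseline Baseline rate (%); must be positive.
#' @param improved Improved rate (%).
#' @return Relative improvement in percent.
#' @export
relativeImprovement <- function(baseline, improved) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  (baseline - improved) / baseline * 100
}

#' Paired t-test on per-subject differences
#'
#' @param diffs Numeric vector of per-subject differences.
#' @param tail `"one"` or `"two"`.
#' @return List with `t`, `df`, `p`.
#' @export
pairedT <- function(diffs, tail = c("one", "two")) {
  tail <- match.arg(tail)
  n <- length(diffs)
  if (n < 2) stop("need at least two subjects")
  s <- stats::sd(diffs)
  if (s == 0) stop("zero variance of differences")
  t <- mean(diffs) / (s / sqrt(n))
  p <- stats::pt(t, df = n - 1, lower.tail = FALSE)
  if (tail == "two") p <- 2 * min(p, 1 - p)
  list(t = t, df = n - 1L, p = p)
}
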