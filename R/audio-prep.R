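# Audio preprocessing (downsampling, declipping) and the 4-class speech
# emotion recognition cross-validation pipeline.

#' Downsample audio from 22050 Hz to 16000 Hz
#'
#' Polyphase FIR resampling at the rational ratio `toRate/fromRate`
#' (320/441 for the platform's rates). The output length is
#' `round(n * toRate/fromRate)`.
#'
#' @param waveform Mono numeric vector.
#' @param fromRate Input rate, Hz (default 22050).
#' @param toRate Output rate, Hz (default 16000).
#' @return Numeric vector at `toRate`.
#' @export
downsampleAudio <- function(waveform, fromRate = 22050, toRate = 16000) {
  if (!length(waveform)) stop("empty input")
  g <- .gcd(fromRate, toRate)
  p <- toRate / g; q <- fromRate / g
  out <- signal::resample(waveform, p, q)
  nOut <- round(length(waveform) * toRate / fromRate)
  if (length(out) >= nOut) out[seq_len(nOut)]
  else c(out, rep(0, nOut - length(out)))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Restore clipped regions of a waveform
#'
#' Maximal runs of samples whose magnitude reaches `thresholdFrac` of the
#' waveform's observed maximum are treated as clipped and replaced by a
#' polynomial interpolant fitted through 4 unclipped flanking samples on
#' each side (quartic least squares, so a flat-topped peak is rebuilt
#' symmetrically from both shoulders). Restored peaks may exceed the clip
#' level; samples outside clipped runs are untouched.
#'
#' @param waveform Mono numeric vector in `[-1, 1]`.
#' @param thresholdFrac Clip threshold as a fraction of the observed
#'   maximum magnitude (default 0.70).
#' @param flank Clean samples used on each side of a run (default 4).
#' @param flatTol Sample-to-sample change (as a fraction of the maximum
#'   magnitude) below which consecutive above-threshold samples count as a
#'   clipped plateau rather than genuine loud signal (default 1e-3).
#' @return The restored waveform.
#' @export
declip <- function(waveform, thresholdFrac = 0.70, flank = 4,
                   flatTol = 1e-3) {
  n <- length(waveform)
  if (!n) stop("empty input")
  thr <- thresholdFrac * max(abs(waveform))
  clipped <- abs(waveform) >= thr
  if (!any(clipped)) return(waveform)
  if (all(clipped)) stop("fully clipped signal cannot be restored")
  # within each above-threshold run, only the flattened tops are clipping:
  # maximal sub-runs of (near-)constant value of length >= 2, or an
  # isolated single sample above threshold. Loud but wiggly stretches are
  # genuine signal and stay untouched.
  eps <- flatTol * max(abs(waveform))
  runs <- .maskRuns(clipped)  # 0-based starts
  replace <- logical(n)
  for (r in seq_len(nrow(runs))) {
    lo <- runs[r, 1] + 1
    hi <- lo + runs[r, 2] - 1
    if (lo == hi) { replace[lo] <- TRUE; next }
    vals <- waveform[lo:hi]
    grp <- cumsum(c(TRUE, abs(diff(vals)) > eps))
    flatLen <- ave(grp, grp, FUN = length)
    replace[(lo:hi)[flatLen >= 2]] <- TRUE
  }
  if (!any(replace)) return(waveform)
  out <- waveform
  repIdx <- which(replace)
  gaps <- .maskRuns(replace)
  # the threshold semantics imply the clip ceiling sits at thresholdFrac
  # of the true full scale, which bounds any restored peak
  cap <- max(abs(waveform)) / thresholdFrac
  for (r in seq_len(nrow(gaps))) {
    lo <- gaps[r, 1] + 1
    hi <- lo + gaps[r, 2] - 1
    left <- if (lo > 1)
      utils::tail(setdiff(seq(max(1, lo - 3 * flank), lo - 1), repIdx),
                  flank) else integer()
    right <- if (hi < n)
      utils::head(setdiff(seq(hi + 1, min(n, hi + 3 * flank)), repIdx),
                  flank) else integer()
    anchors <- c(left, right)
    # quartic least-squares through the flanks: the even term lets a
    # flattened peak be rebuilt symmetrically from both shoulders, and a
    # run at the signal edge degrades gracefully to a lower degree
    deg <- min(4L, length(anchors) - 1L)
    if (deg < 1) next
    xa <- anchors - lo  # centred index keeps the fit well-conditioned
    fit <- stats::lm.fit(outer(xa, 0:deg, "^"), waveform[anchors])
    xg <- (lo:hi) - lo
    vals <- drop(outer(xg, 0:deg, "^") %*% fit$coefficients)
    # restored peaks keep the plateau's sign and never reduce amplitude
    # below the clip level; the polynomial must not overshoot either.
    # (an isolated single sample is an artifact, not a flattened peak,
    # so the amplitude floor does not apply to it)
    sgn <- if (hi > lo) sign(mean(waveform[lo:hi])) else 0
    if (sgn != 0) {
      level <- sgn * max(abs(waveform[lo:hi]))
      bad <- sign(vals) != sgn | abs(vals) < abs(level)
      vals[bad] <- level
    }
    out[lo:hi] <- pmin(pmax(vals, -cap), cap)
  }
  out
}

# --- SER feature extraction ---------------------------------------------

#' Utterance-level SER features
#'
#' Frame-level descriptors (25 ms frames, 10 ms hop, Hamming window):
#' log energy, fundamental-frequency estimate (autocorrelation, 50-500 Hz),
#' spectral centroid, 85% spectral rolloff, and 13 real-cepstrum
#' coefficients. Each descriptor is summarized over frames by mean, SD,
#' 20th/80th percentiles, and linear slope, giving an 85-dimensional
#' utterance vector.
#'
#' @param waveform Mono numeric vector at `rate` Hz.
#' @param rate Sampling rate, Hz (default 16000).
#' @return Named numeric feature vector.
#' @export
serFeatures <- function(waveform, rate = 16000) {
  frameLen <- round(0.025 * rate)
  hop <- round(0.010 * rate)
  nF <- max(1L, floor((length(waveform) - frameLen) / hop) + 1L)
  starts <- (seq_len(nF) - 1L) * hop + 1L
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, frameLen - 1) / (frameLen - 1))
  frames <- vapply(starts, function(s)
    waveform[s:(s + frameLen - 1)] * win, numeric(frameLen))
  nfft <- 2^ceiling(log2(frameLen))
  padded <- rbind(frames, matrix(0, nfft - frameLen, nF))
  spec <- abs(stats::mvfft(padded))[seq_len(nfft / 2), , drop = FALSE]
  freqs <- (seq_len(nfft / 2) - 1) * rate / nfft
  energy <- log(colSums(frames^2) + 1e-12)
  centroid <- colSums(spec * freqs) / (colSums(spec) + 1e-12)
  rolloff <- apply(spec, 2, function(m) {
    cs <- cumsum(m)
    freqs[which(cs >= 0.85 * cs[length(cs)])[1]]
  })
  # f0 by autocorrelation peak in the 50-500 Hz lag range
  lagMin <- floor(rate / 500); lagMax <- min(ceiling(rate / 50), frameLen - 1)
  f0 <- apply(frames, 2, function(fr) {
    ac <- stats::acf(fr, lag.max = lagMax, plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    seg <- ac[(lagMin + 1):(lagMax + 1)]
    pk <- which.max(seg)
    if (seg[pk] < 0.2) 0 else rate / (lagMin + pk - 1)
  })
  # real cepstrum, first 13 coefficients
  logSpec <- log(abs(stats::mvfft(padded)) + 1e-12)
  ceps <- Re(stats::mvfft(logSpec, inverse = TRUE)) / nfft
  ceps <- ceps[seq_len(13), , drop = FALSE]
  desc <- rbind(energy = energy, f0 = f0, centroid = centroid,
                rolloff = rolloff, ceps)
  rownames(desc) <- c("energy", "f0", "centroid", "rolloff",
                      paste0("cep", 1:13))
  t <- seq_len(nF)
  fn <- function(v) c(mean = mean(v), sd = stats::sd(v),
                      p20 = unname(stats::quantile(v, 0.2)),
                      p80 = unname(stats::quantile(v, 0.8)),
                      slope = if (nF > 1) unname(stats::coef(
                        stats::lm.fit(cbind(1, t), v))[2]) else 0)
  out <- as.vector(apply(desc, 1, fn))
  names(out) <- as.vector(outer(c("mean", "sd", "p20", "p80", "slope"),
                                rownames(desc), function(a, b)
                                  paste(b, a, sep = ".")))
  out[!is.finite(out)] <- 0
  out
}

#' Speech emotion recognition cross-validation
#'
#' Utterance-level [serFeatures()] are classified with linear discriminant
#' analysis under stratified k-fold cross-validation (stratified by emotion;
#' the corpus is too small for speaker-independent folds). Constant feature
#' columns are dropped with a warning. Deterministic given
#' `(utterances, seed)`.
#'
#' @param utterances List of mono waveforms at `rate` Hz, or a precomputed
#'   utterances x features matrix (used as-is).
#' @param emotions Emotion label per utterance.
#' @param folds Number of folds (default 3).
#' @param seed Seed for the fold assignment.
#' @param rate Sampling rate of the waveforms, Hz.
#' @return List with `confusion` (pooled, rows = truth), `pooled` metrics,
#'   `perFold` data frame, and `correct` (per-utterance logical, in input
#'   order) for paired testing.
#' @export
serCrossval <- function(utterances, emotions, folds = 3, seed = 1,
                        rate = 16000) {
  emotions <- factor(emotions)
  classes <- levels(emotions)
  X <- if (is.matrix(utterances)) utterances
       else t(vapply(utterances, serFeatures, serFeatures(utterances[[1]],
                                                          rate), rate))
  n <- nrow(X)
  stopifnot(length(emotions) == n)
  # degenerate columns (constant overall or within any class) break the
  # discriminant's within-group covariance; drop them up front
  X <- scale(X)
  X[!is.finite(X)] <- 0
  keep <- apply(X, 2, function(col) {
    stats::sd(col) > 1e-6 &&
      all(vapply(classes, function(cl)
        stats::sd(col[emotions == cl]), numeric(1)) > 1e-3)
  })
  if (any(!keep)) {
    warning(sprintf("dropped %d constant feature column(s)", sum(!keep)))
    X <- X[, keep, drop = FALSE]
  }
  set.seed(seed)
  fold <- integer(n)
  for (cl in classes) {
    i <- sample(which(emotions == cl))
    fold[i] <- rep_len(seq_len(folds), length(i))
  }
  if (!all(vapply(seq_len(folds), function(f)
    all(classes %in% emotions[fold == f]), logical(1))))
    stop("every fold must contain all classes; corpus too small")
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  correct <- logical(n)
  perFold <- NULL
  for (f in seq_len(folds)) {
    te <- which(fold == f); tr <- which(fold != f)
    fit <- MASS::lda(X[tr, , drop = FALSE], grouping = emotions[tr])
    pred <- stats::predict(fit, X[te, , drop = FALSE])$class
    cm <- table(factor(emotions[te], classes), factor(pred, classes))
    pooled <- pooled + cm
    correct[te] <- pred == emotions[te]
    met <- classifierMetrics(cm)
    perFold <- rbind(perFold, data.frame(
      fold = f, accuracy = met["accuracy"],
      weightedF1 = met["weightedF1"], kappa = met["kappa"]))
  }
  rownames(perFold) <- NULL
  list(confusion = pooled, pooled = classifierMetrics(pooled),
       perFold = perFold, correct = correct)
}
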