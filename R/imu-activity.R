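# Accelerometer preprocessing and four-class activity recognition, plus the
# gyroscope rotation rule.

#' Remove the gravity component from 3-axis accelerometer data
#'
#' The gravity-bearing axis is identified as the axis whose low-pass
#' (0.25 Hz) mean magnitude is largest; 9.8 m/s^2 is subtracted from that
#' axis with matching sign. Assumes the device orientation is quasi-static
#' over the window.
#'
#' @param accel n x 3 matrix (m/s^2).
#' @param rate Sampling rate in Hz (default 70).
#' @param g Gravitational acceleration subtracted (default 9.8).
#' @return n x 3 matrix with gravity removed.
#' @export
removeGravity <- function(accel, rate = 70, g = 9.8) {
  accel <- as.matrix(accel)
  stopifnot(ncol(accel) == 3)
  bf <- signal::butter(2, min(0.25 / (rate / 2), 0.99), type = "low")
  lp <- apply(accel, 2, function(col) {
    if (length(col) > 12) mean(signal::filtfilt(bf, col)) else mean(col)
  })
  axis <- which.max(abs(lp))
  out <- accel
  out[, axis] <- out[, axis] - sign(lp[axis]) * g
  out
}

#' Resample a dynamic-rate IMU stream to a fixed rate
#'
#' The platform's IMU rate floats within 70 +/- 5 Hz. Using the sample
#' timestamps, each non-overlapping 30 s interval is forced to exactly
#' `targetRate * 30` samples by linear interpolation of the timestamped
#' samples onto the interval's uniform grid (this both up- and
#' down-samples, and keeps the jittered sample clock from leaking phase
#' error into the output). Intervals holding less than half the expected
#' samples are flagged.
#'
#' @param time Numeric vector of sample times (seconds or UTC ms; only
#'   spacing matters, with `intervalS` in the same unit via `timeUnit`).
#' @param values Numeric vector or matrix (one row per sample).
#' @param targetRate Target rate, Hz (default 70).
#' @param intervalS Interval length, seconds (default 30).
#' @return List with `time` (uniform grid), `values`, and `flagged`
#'   (logical per interval: under half the expected samples).
#' @export
resampleDynamic <- function(time, values, targetRate = 70, intervalS = 30) {
  values <- as.matrix(values)
  stopifnot(length(time) == nrow(values))
  if (max(time) - min(time) > 1e7) {  # looks like UTC milliseconds
    time <- (time - min(time)) / 1000
  }
  t0 <- min(time)
  nOut <- round(targetRate * intervalS)
  idx <- floor((time - t0) / intervalS)
  ks <- sort(unique(idx))
  outT <- vector("list", length(ks))
  outV <- vector("list", length(ks))
  flagged <- logical(length(ks))
  for (ki in seq_along(ks)) {
    k <- ks[ki]
    sel <- which(idx == k)
    grid <- t0 + k * intervalS + (seq_len(nOut) - 1) / targetRate
    flagged[ki] <- length(sel) < nOut / 2
    v <- apply(values[sel, , drop = FALSE], 2, function(col)
      stats::approx(time[sel], col, grid, rule = 2)$y)
    v <- matrix(v, nrow = nOut)
    outT[[ki]] <- grid
    outV[[ki]] <- v
  }
  outV <- do.call(rbind, outV)
  colnames(outV) <- colnames(values)
  list(time = unlist(outT), values = outV, flagged = flagged)
}

#' Cut a fixed-rate accelerometer stream into labelled 5 s windows
#'
#' Windows are non-overlapping; windows spanning a label change (activity
#' transitions) are excluded.
#'
#' @param accel n x 3 matrix at `rate` Hz.
#' @param labels Per-sample activity labels.
#' @param rate Sampling rate, Hz (default 70).
#' @param windowS Window length, seconds (default 5).
#' @return List with `features` (windows x (3 * rate * windowS) matrix of
#'   flattened samples) and `label` per window.
#' @export
windowActivity <- function(accel, labels, rate = 70, windowS = 5) {
  n <- nrow(accel)
  wl <- round(rate * windowS)
  nW <- floor(n / wl)
  feats <- vector("list", nW); lab <- character(nW)
  keep <- logical(nW)
  for (k in seq_len(nW)) {
    sel <- ((k - 1) * wl + 1):(k * wl)
    ls <- unique(labels[sel])
    if (length(ls) != 1) next  # transition window
    feats[[k]] <- as.vector(accel[sel, ])
    lab[k] <- ls
    keep[k] <- TRUE
  }
  list(features = do.call(rbind, feats[keep]), label = lab[keep])
}

#' Four-class activity classification with repeated stratified splits
#'
#' A 100-tree random forest on flattened normalized window samples,
#' evaluated over `nSplits` repeated stratified random 80/20 train/test
#' splits. Normalization (centre/scale per feature) is fitted on the
#' training split only. Test-fold predictions are pooled into one confusion
#' matrix; accuracy, class-frequency-weighted F1, and Cohen's kappa are
#' reported per split and pooled.
#'
#' @param features Windows x features numeric matrix.
#' @param labels Window labels (factor or character).
#' @param nSplits Number of repeated splits (default 10).
#' @param trainFrac Training fraction (default 0.8).
#' @param nTrees Trees per forest (default 100).
#' @param seed Seed controlling the split sequence and forests.
#' @return List with `confusion` (pooled, rows = truth), `pooled` (named
#'   accuracy/weightedF1/kappa), `perSplit` (data frame), and `correct`
#'   (pooled logical correctness vector over test predictions).
#' @export
classifyActivities <- function(features, labels, nSplits = 10,
                               trainFrac = 0.8, nTrees = 100, seed = 1) {
  labels <- factor(labels)
  classes <- levels(labels)
  if (length(classes) < 2) stop("need at least two classes")
  n <- nrow(features)
  set.seed(seed)
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  perSplit <- NULL
  correct <- logical()
  for (s in seq_len(nSplits)) {
    repeat {  # stratified split; resample if a class misses a side
      trainIdx <- unlist(lapply(classes, function(cl) {
        i <- which(labels == cl)
        sample(i, max(1, round(trainFrac * length(i))))
      }))
      testIdx <- setdiff(seq_len(n), trainIdx)
      if (all(classes %in% labels[trainIdx]) &&
          all(classes %in% labels[testIdx])) break
    }
    mu <- colMeans(features[trainIdx, , drop = FALSE])
    sd <- apply(features[trainIdx, , drop = FALSE], 2, stats::sd)
    sd[sd == 0] <- 1
    tr <- scale(features[trainIdx, , drop = FALSE], mu, sd)
    te <- scale(features[testIdx, , drop = FALSE], mu, sd)
    colnames(tr) <- colnames(te) <- paste0("f", seq_len(ncol(tr)))
    fit <- ranger::ranger(x = tr, y = labels[trainIdx], num.trees = nTrees,
                          num.threads = 1, seed = seed + s)
    pred <- stats::predict(fit, te, num.threads = 1)$predictions
    cm <- table(factor(labels[testIdx], classes), factor(pred, classes))
    pooled <- pooled + cm
    met <- classifierMetrics(cm)
    perSplit <- rbind(perSplit, data.frame(
      split = s, accuracy = met["accuracy"],
      weightedF1 = met["weightedF1"], kappa = met["kappa"]))
    correct <- c(correct, pred == labels[testIdx])
  }
  rownames(perSplit) <- NULL
  list(confusion = pooled, pooled = classifierMetrics(pooled),
       perSplit = perSplit, correct = correct)
}

#' Rule-based rotation detection from gyroscope data
#'
#' A window is labelled a rotation when the absolute cumulative integral of
#' any single gyroscope axis reaches `thresholdDeg` within the window
#' (default 300 degrees, tolerating integration leakage below a full 360).
#'
#' @param gyro n x 3 matrix, deg/s.
#' @param rate Sampling rate, Hz (default 70).
#' @param windowS Window length, seconds (default 5).
#' @param thresholdDeg Cumulative-rotation threshold, degrees.
#' @return Logical vector, one entry per non-overlapping window.
#' @export
detectRotation <- function(gyro, rate = 70, windowS = 5,
                           thresholdDeg = 300) {
  gyro <- as.matrix(gyro)
  wl <- round(rate * windowS)
  nW <- floor(nrow(gyro) / wl)
  vapply(seq_len(nW), function(k) {
    seg <- gyro[((k - 1) * wl + 1):(k * wl), , drop = FALSE]
    any(apply(seg, 2, function(a) max(abs(cumsum(a)))) / rate >= thresholdDeg)
  }, logical(1))
}
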