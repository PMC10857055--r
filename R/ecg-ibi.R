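# R-peak detection, IBI artifact editing, and session segmentation.

#' Detect R-peaks in an ECG trace
#'
#' A Pan-Tompkins-style pipeline: band-limit to 5-20 Hz (3rd-order
#' Butterworth, zero-phase), differentiate, square, integrate over a 150 ms
#' moving window, then pick peaks above an adaptive threshold with a 200 ms
#' refractory period. Each integrator peak is refined to the R-wave maximum
#' of the band-limited signal in the preceding 150 ms, and beat times are
#' quantized to the 4 ms grid of the 250 Hz IBI clock.
#'
#' @param ecg Numeric vector of ECG samples (ADC counts), or a
#'   [SensorChunk-class] of modality `"ecg"`.
#' @param rate Sampling rate in Hz (default 2426, the platform's ECG rate).
#' @param config Optional list overriding `band` (Hz), `integrateMs`,
#'   `refractoryMs`, `thresholdFrac` (fraction of the running signal-peak
#'   estimate).
#' @return Numeric vector of beat times in seconds from trace start, on the
#'   4 ms grid.
#' @export
detectRPeaks <- function(ecg, rate = 2426, config = list()) {
  if (methods::is(ecg, "SensorChunk")) {
    rate <- ecg@nominalRate
    ecg <- chunkSamples(ecg)
  }
  cfg <- utils::modifyList(list(band = c(5, 20), integrateMs = 150,
                                refractoryMs = 200, thresholdFrac = 0.35),
                           config)
  if (length(ecg) < 10 * rate) stop("need at least 10 s of ECG signal")
  if (stats::sd(ecg) == 0) stop("no peaks: flat signal")
  bf <- signal::butter(3, cfg$band / (rate / 2), type = "pass")
  filt <- signal::filtfilt(bf, ecg - mean(ecg))
  if (max(abs(filt)) == 0) stop("no peaks: flat signal after filtering")
  deriv <- c(0, diff(filt))
  sq <- deriv^2
  w <- max(1L, round(cfg$integrateMs / 1000 * rate))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  integ[is.na(integ)] <- 0
  refr <- round(cfg$refractoryMs / 1000 * rate)
  # local maxima of the integrated signal
  isPk <- which(diff(sign(diff(integ))) < 0) + 1L
  if (!length(isPk)) stop("no peaks found")
  spki <- stats::quantile(integ[isPk], 0.95)
  peaks <- integer()
  lastPk <- -Inf
  for (i in isPk) {
    if (integ[i] >= cfg$thresholdFrac * spki) {
      if (i - lastPk > refr) {
        peaks <- c(peaks, i)
        lastPk <- i
        spki <- 0.125 * integ[i] + 0.875 * spki
      } else if (integ[i] > integ[lastPk]) {
        peaks[length(peaks)] <- i  # larger peak inside refractory window
        lastPk <- i
      }
    }
  }
  if (length(peaks) < 2) stop("no peaks: fewer than two beats detected")
  # refine to the R maximum of the band-limited signal: the integrator peak
  # trails the R wave by roughly the integration window
  beat <- vapply(peaks, function(i) {
    lo <- max(1L, i - w)
    lo + which.max(filt[lo:i]) - 1L
  }, numeric(1))
  beat <- sort(unique(beat))
  round(((beat - 1) / rate) / 0.004) * 0.004
}

.localMedian <- function(x, i, k = 5) {
  # median of the k nearest neighbours by index, excluding i
  n <- length(x)
  ord <- order(abs(seq_len(n) - i))
  nb <- setdiff(ord, i)[seq_len(min(k, n - 1))]
  stats::median(x[nb])
}

#' Flag and edit IBI artifacts, including missing-sample artifacts
#'
#' Intervals overlapping zero-padded stretches of the source ECG are flagged
#' `missing_overlap`. Flagged intervals, intervals outside the physiological
#' bounds, and intervals deviating more than `deviationFrac` from the median
#' of their 5 nearest neighbours are edited with the standard divide /
#' combine / interpolate rules:
#' \itemize{
#'   \item a long interval close to an integer multiple `k >= 2` of the
#'     local median (within `multipleTol`) is divided into `k` equal parts
#'     (`edited_divide`);
#'   \item a short pair of adjacent intervals whose sum is close to the
#'     local median is combined (`edited_combine`);
#'   \item anything else is replaced by linear interpolation between
#'     neighbouring clean intervals, rescaled so the run keeps its total
#'     duration (`edited_interpolate`).
#' }
#' The edited fraction is recorded on the result; when it exceeds
#' `unusableFrac` the series is marked unusable with a warning.
#'
#' @param ibi An [IBISeries-class].
#' @param paddingIntervals Optional two-column matrix or data frame of
#'   (start, end) times in seconds during which the ECG was zero-padded.
#' @param subjectClass `"adult"` (bounds 300-2000 ms) or `"infant"`
#'   (250-1000 ms); ignored when `bounds` is given.
#' @param bounds Optional explicit (low, high) physiological bounds, ms.
#' @param config Optional list overriding `neighbours` (5), `deviationFrac`
#'   (0.25), `multipleTol` (0.125), `unusableFrac` (0.20).
#' @return An edited [IBISeries-class].
#' @export
correctMissingArtifacts <- function(ibi, paddingIntervals = NULL,
                                    subjectClass = c("adult", "infant"),
                                    bounds = NULL, config = list()) {
  subjectClass <- match.arg(subjectClass)
  if (is.null(bounds))
    bounds <- if (subjectClass == "adult") c(300, 2000) else c(250, 1000)
  cfg <- utils::modifyList(list(neighbours = 5, deviationFrac = 0.25,
                                multipleTol = 0.125, unusableFrac = 0.20),
                           config)
  bt <- ibi@beatTimes
  v <- ibi@ibiMs
  fl <- ibi@flags
  n <- length(v)
  if (!n) return(ibi)

  overlaps <- rep(FALSE, n)
  if (!is.null(paddingIntervals) && NROW(paddingIntervals) > 0) {
    pi <- as.matrix(paddingIntervals)
    for (r in seq_len(nrow(pi)))
      overlaps <- overlaps | (bt[-(n + 1)] < pi[r, 2] & bt[-1] > pi[r, 1])
  }
  fl[overlaps & fl == "ok"] <- "missing_overlap"

  suspect <- function(vals, i) {
    m <- .localMedian(vals, i, cfg$neighbours)
    vals[i] < bounds[1] || vals[i] > bounds[2] ||
      abs(vals[i] - m) / m > cfg$deviationFrac
  }

  newBt <- list(bt[1])
  newV <- numeric()
  newFl <- character()
  nEdits <- 0
  i <- 1
  while (i <= n) {
    m <- .localMedian(v, i, cfg$neighbours)
    bad <- fl[i] == "missing_overlap" || suspect(v, i)
    if (!bad) {
      newV <- c(newV, v[i]); newFl <- c(newFl, fl[i])
      newBt <- c(newBt, bt[i + 1]); i <- i + 1
      next
    }
    nEdits <- nEdits + 1
    k <- round(v[i] / m)
    if (k >= 2 && abs(v[i] - k * m) <= cfg$multipleTol * k * m) {
      # divide into k parts on the 4 ms grid; last part takes the remainder
      part <- round(v[i] / k / 4) * 4
      parts <- c(rep(part, k - 1), v[i] - part * (k - 1))
      newV <- c(newV, parts); newFl <- c(newFl, rep("edited_divide", k))
      newBt <- c(newBt, bt[i] + cumsum(parts) / 1000)
      i <- i + 1
    } else if (i < n &&
               (fl[i + 1] == "missing_overlap" || suspect(v, i + 1)) &&
               abs(v[i] + v[i + 1] - m) <= cfg$multipleTol * m) {
      newV <- c(newV, v[i] + v[i + 1])
      newFl <- c(newFl, "edited_combine")
      newBt <- c(newBt, bt[i + 2]); i <- i + 2
    } else {
      # absorb the whole suspect run, then redistribute its span across as
      # many intervals as the local median implies (beats lost in padded
      # gaps are re-inserted), linearly blending the flanking values
      j <- i
      while (j < n && (fl[j + 1] == "missing_overlap" || suspect(v, j + 1)))
        j <- j + 1
      span <- (bt[j + 1] - bt[i]) * 1000
      left <- if (length(newV))
        stats::median(utils::tail(newV, 3)) else m
      right <- if (j < n)
        stats::median(v[(j + 1):min(n, j + 3)]) else m
      nn <- max(1, round(span / m))
      raw <- left + (right - left) * seq_len(nn) / (nn + 1)
      vals <- raw * span / sum(raw)
      vals <- round(vals / 4) * 4
      vals[nn] <- span - sum(vals[-nn])
      newV <- c(newV, vals)
      newFl <- c(newFl, rep("edited_interpolate", nn))
      newBt <- c(newBt, bt[i] + cumsum(vals) / 1000)
      nEdits <- nEdits + (j - i)
      i <- j + 1
    }
  }
  out <- IBISeries(unlist(newBt))
  out@flags <- newFl
  out@session <- rep("", length(newV))
  out@editedFraction <- nEdits / n
  if (out@editedFraction > cfg$unusableFrac) {
    out@unusable <- TRUE
    warning(sprintf("%.1f%% of intervals needed editing; series marked unusable",
                    100 * out@editedFraction))
  }
  methods::validObject(out)
  out
}

#' Segment an IBI series by session
#'
#' Intervals are assigned to a session when their beat midpoint falls inside
#' the session window.
#'
#' @param ibi An [IBISeries-class].
#' @param sessionTable Data frame with columns `label`, `start_s`, `end_s`;
#'   sessions must not overlap.
#' @return Named list of [IBISeries-class], one per session row. A session
#'   with no intervals yields an empty series with a warning.
#' @export
segmentSessions <- function(ibi, sessionTable) {
  st <- as.data.frame(sessionTable)
  stopifnot(all(c("label", "start_s", "end_s") %in% names(st)))
  o <- order(st$start_s)
  if (any(st$end_s[o][-nrow(st)] > st$start_s[o][-1] + 1e-9))
    stop("sessions overlap")
  mid <- (ibi@beatTimes[-length(ibi@beatTimes)] + ibi@beatTimes[-1]) / 2
  out <- list()
  for (r in seq_len(nrow(st))) {
    sel <- which(mid >= st$start_s[r] & mid < st$end_s[r])
    if (!length(sel)) {
      warning(sprintf("session '%s' contains no intervals", st$label[r]))
      out[[st$label[r]]] <- IBISeries(numeric())
      next
    }
    s <- IBISeries(ibi@beatTimes[c(sel, max(sel) + 1L)])
    s@flags <- ibi@flags[sel]
    s@session <- rep(st$label[r], length(sel))
    out[[st$label[r]]] <- s
  }
  out
}

#' Extract an artifact-edited IBI series from an ECG recording
#'
#' Convenience wrapper over the full ECG chain: UTC framing with
#' zero-padding ([frameStreams()]), R-peak detection ([detectRPeaks()]),
#' and padding-aware artifact editing ([correctMissingArtifacts()], fed
#' the padded stretches from the frame masks).
#'
#' @param recording A [Recording-class] containing ECG chunks.
#' @param subjectClass `"adult"` or `"infant"` (editing bounds).
#' @param config Optional editing config passed through.
#' @return An edited [IBISeries-class]; times are seconds from the first
#'   frame start.
#' @export
extractIbi <- function(recording, subjectClass = "adult", config = list()) {
  fr <- frameStreams(recording)
  if (is.null(fr$ecg)) stop("recording has no ECG chunks")
  ecg <- unlist(lapply(fr$ecg, `[[`, "samples"))
  mask <- unlist(lapply(fr$ecg, `[[`, "missingMask"))
  rate <- nominalRateOf("ecg")
  # detect on a baseline-filled copy: leaving the padding at literal zero
  # would put large filter transients at every gap edge and corrupt the
  # beats next to it; the padded stretches stay flagged for editing
  if (any(mask)) ecg[mask] <- stats::median(ecg[!mask])
  beats <- detectRPeaks(ecg, rate)
  pad <- NULL
  if (any(mask)) {
    runs <- .maskRuns(mask)
    pad <- cbind(runs[, 1] / rate, (runs[, 1] + runs[, 2]) / rate)
  }
  correctMissingArtifacts(IBISeries(beats), pad,
                          subjectClass = subjectClass, config = config)
}

#' Write an IBI series to CSV
#'
#' Columns: `beat_time_s` (interval start), `ibi_ms`, `flag`, `session`.
#'
#' @param ibi An [IBISeries-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeIbiCsv <- function(ibi, path) {
  n <- length(ibi@ibiMs)
  utils::write.csv(data.frame(
    beat_time_s = ibi@beatTimes[seq_len(n)],
    ibi_ms = ibi@ibiMs, flag = ibi@flags, session = ibi@session),
    path, row.names = FALSE)
  invisible(path)
}

#' Read an IBI series from CSV
#'
#' @param path CSV written by [writeIbiCsv()].
#' @return An [IBISeries-class].
#' @export
readIbiCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bt <- c(df$beat_time_s, df$beat_time_s[nrow(df)] +
            df$ibi_ms[nrow(df)] / 1000)
  s <- IBISeries(bt)
  s@flags <- df$flag
  s@session <- as.character(df$session)
  s
}
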