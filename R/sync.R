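# UTC-based frame synchronization: splitting chunk streams into aligned
# frames, zero-padding short frames, and estimating lags between devices.

#' Split a recording into UTC-aligned frames
#'
#' Frames for all modalities share a common UTC origin (the earliest chunk
#' start in the recording); each modality is cut on its own period grid
#' anchored at that origin. Every frame holds exactly
#' `round(framePeriod * nominalRate)` samples: samples are placed by their
#' UTC timestamps and any deficit is zero-padded with the missing mask set.
#' Samples already flagged as padding in the input keep their flag.
#'
#' @param recording A valid [Recording-class].
#' @param framePeriod Named numeric vector of frame periods in seconds per
#'   modality; defaults to the write cadence (30 s ECG/IMU, 10 s audio).
#' @return Named list (per modality present) of lists of frames; each frame
#'   is a list with `modality`, `frameStartUTC` (ms), `framePeriod` (s),
#'   `samples`, and `missingMask`.
#' @export
frameStreams <- function(recording,
                         framePeriod = c(ecg = 30, imu = 30, audio = 10)) {
  methods::validObject(recording)
  if (!length(recording@chunks)) return(list())
  origin <- min(vapply(recording@chunks, startUTC, numeric(1)))
  out <- list()
  for (m in MODALITIES) {
    ch <- chunks(recording, m)
    if (!length(ch)) next
    period <- unname(framePeriod[[m]])
    rate <- ch[[1]]@nominalRate
    frameLen <- round(period * rate)
    # pool samples with their UTC stamps
    utc <- unlist(lapply(ch, .sampleUTC))
    mask <- unlist(lapply(ch, missingMask))
    isMat <- ch[[1]]@modality == "imu"
    smp <- if (isMat) do.call(rbind, lapply(ch, chunkSamples))
           else unlist(lapply(ch, chunkSamples))
    idx <- floor((utc - origin) / (period * 1000))
    frames <- list()
    for (k in sort(unique(idx))) {
      fStart <- origin + k * period * 1000
      sel <- which(idx == k)
      # position within the frame from the timestamp, clipped to the grid
      pos <- pmin(pmax(round((utc[sel] - fStart) / 1000 * rate) + 1, 1),
                  frameLen)
      fMask <- rep(TRUE, frameLen)
      if (isMat) {
        fSmp <- matrix(0, frameLen, 9, dimnames = list(NULL, IMU_CHANNELS))
        fSmp[pos, ] <- smp[sel, ]
      } else {
        fSmp <- numeric(frameLen)
        fSmp[pos] <- smp[sel]
      }
      fMask[pos] <- mask[sel]
      if (any(fMask)) {
        if (isMat) fSmp[fMask, ] <- 0 else fSmp[fMask] <- 0
      }
      frames[[length(frames) + 1L]] <- list(
        modality = m, frameStartUTC = fStart, framePeriod = period,
        samples = fSmp, missingMask = fMask)
    }
    out[[m]] <- frames
  }
  out
}

#' Estimate the lag between two irregularly sampled series
#'
#' Both series are step-interpolated onto a common 0.1 s grid and the lag
#' minimizing the mean absolute difference over a grid of candidate lags is
#' returned; ties break toward the smallest absolute lag. When the best
#' objective improves on the zero-lag objective by less than 5% the
#' estimate is flagged low-confidence.
#'
#' @param a,b Lists or data frames with `time` (s) and `value` components.
#' @param maxLag Maximum absolute lag searched, seconds (default 30).
#' @param step Lag grid step, seconds (default 0.1).
#' @return List with `lag` (s; the estimated shift of `b` relative to
#'   `a`, so `b$time - lag` matches `a`), `objective`, `lowConfidence`,
#'   and the aligned series `a` and `bShifted`.
#' @export
alignSeries <- function(a, b, maxLag = 30, step = 0.1) {
  if (!length(a$time) || !length(b$time)) stop("empty series")
  if (diff(range(a$time)) < 2 * maxLag || diff(range(b$time)) < 2 * maxLag)
    stop("series must span at least twice maxLag")
  lags <- seq(-maxLag, maxLag, by = step)
  grid <- seq(max(min(a$time), min(b$time) - maxLag),
              min(max(a$time), max(b$time) + maxLag), by = step)
  av <- stats::approx(a$time, a$value, grid, method = "constant",
                      rule = 2)$y
  obj <- vapply(lags, function(l) {
    # candidate l is the hypothesised shift of b relative to a
    bv <- stats::approx(b$time - l, b$value, grid, method = "constant",
                        rule = 2)$y
    mean(abs(av - bv))
  }, numeric(1))
  best <- which(obj == min(obj))
  best <- best[which.min(abs(lags[best]))]
  lag <- lags[best]
  obj0 <- obj[which.min(abs(lags))]
  # a perfect zero-lag match is fully confident; otherwise require a >=5%
  # improvement over lag 0 before trusting the estimate (short noisy
  # series can beat this by chance, so confidence grows with length)
  lowConfidence <- obj0 > 1e-12 && (obj0 - obj[best]) / obj0 < 0.05
  list(lag = lag, objective = obj[best], lowConfidence = lowConfidence,
       a = a, bShifted = list(time = b$time - lag, value = b$value))
}
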