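# Seeded synthetic fixtures: prescribed-IBI ECG with respiratory
# modulation, per-activity accelerometer/gyro traces, emotional-speech
# surrogates, and chunk-level degradation (sample loss, clock drift).

#' Generate a synthetic ECG recording with prescribed IBI
#'
#' Beat times integrate an instantaneous heart period
#' `base + amp * sin(2*pi*hz*t)` per session; each beat stamps a QRS-like
#' template (three Gaussians: Q/R/S deflections of relative amplitude
#' -0.15/1.0/-0.25 and widths 10/12/10 ms) onto a constant baseline with
#' optional Gaussian noise. No morphological realism beyond a sharp,
#' detectable R wave is intended.
#'
#' @param schedule Data frame with columns `label`, `duration_s`,
#'   `base_ms`, `amp_ms`, `hz` (one row per session, in order).
#' @param noiseSd Gaussian noise SD in ADC counts (default 0).
#' @param seed Integer seed.
#' @param rate ECG sampling rate, Hz.
#' @param startUTC Recording start, UTC ms.
#' @param rAmp R-wave amplitude in ADC counts.
#' @param firmwareVersion `"v1"` or `"v2"`.
#' @return List with `recording` ([Recording-class] of 30 s ECG chunks),
#'   `beatTimes` (ground truth, s), `ibiMs` (prescribed intervals), and
#'   `sessions` (the session table with realized `start_s`/`end_s`).
#' @export
genEcg <- function(schedule, noiseSd = 0, seed = 1, rate = 2426,
                   startUTC = 1.7e12, rAmp = 800,
                   firmwareVersion = "v2") {
  schedule <- as.data.frame(schedule)
  if (any(schedule$amp_ms >= schedule$base_ms))
    stop("modulation amplitude must be below the base interval")
  set.seed(seed)
  totalS <- sum(schedule$duration_s)
  beats <- numeric(); off <- 0
  starts <- cumsum(c(0, schedule$duration_s))
  for (r in seq_len(nrow(schedule))) {
    t <- starts[r]
    while (t < starts[r + 1]) {
      ibi <- schedule$base_ms[r] +
        schedule$amp_ms[r] * sin(2 * pi * schedule$hz[r] * (t - starts[r]))
      beats <- c(beats, t)
      t <- t + ibi / 1000
    }
  }
  nSamp <- ceiling(totalS * rate)
  tGrid <- (seq_len(nSamp) - 1) / rate
  ecg <- rep(2048, nSamp)
  # Q/R/S Gaussian deflections; widths are FWHM-like (sd = width/3)
  defl <- list(c(-0.025, -0.15, 10), c(0, 1, 12), c(0.025, -0.25, 10))
  for (d in defl) {
    sdS <- d[3] / 3 / 1000
    for (b in beats) {
      ctr <- b + d[1]
      lo <- max(1L, floor((ctr - 4 * sdS) * rate) + 1L)
      hi <- min(nSamp, ceiling((ctr + 4 * sdS) * rate) + 1L)
      if (lo > hi) next
      seg <- tGrid[lo:hi]
      ecg[lo:hi] <- ecg[lo:hi] +
        d[2] * rAmp * exp(-((seg - ctr)^2) / (2 * sdS^2))
    }
  }
  if (noiseSd > 0) ecg <- ecg + stats::rnorm(nSamp, 0, noiseSd)
  chunkLen <- 30 * rate
  chunks <- list()
  for (k in seq_len(ceiling(nSamp / chunkLen))) {
    lo <- (k - 1) * chunkLen + 1
    hi <- min(nSamp, k * chunkLen)
    if (hi - lo + 1 < chunkLen) break  # drop trailing partial chunk
    chunks[[k]] <- SensorChunk("ecg", startUTC + (lo - 1) / rate * 1000,
                               startUTC + hi / rate * 1000, ecg[lo:hi])
  }
  sessions <- data.frame(label = schedule$label,
                         start_s = starts[-length(starts)],
                         end_s = starts[-1])
  list(recording = Recording(chunks, firmwareVersion = firmwareVersion),
       beatTimes = beats, ibiMs = diff(beats) * 1000, sessions = sessions)
}

.ACTIVITY_PARAMS <- list(
  # axis: 1 = x (lateral), 3 = z (vertical); freq Hz; amp m/s^2
  upright = list(axis = 3, freq = 0, amp = 0),
  walk    = list(axis = 3, freq = 2.0, amp = 2.0),
  glide   = list(axis = 1, freq = 1.0, amp = 1.5),
  squat   = list(axis = 3, freq = 0.5, amp = 4.0),
  rotate  = list(axis = 3, freq = 0, amp = 0, gyro = 60)
)

#' Generate a synthetic IMU activity stream
#'
#' Activity signatures: upright = gravity plus low noise; walk = 2 Hz
#' vertical oscillation; glide = 1 Hz lateral oscillation; squat = 0.5 Hz
#' high-amplitude vertical oscillation; rotate = sustained single-axis
#' gyroscope rate (~60 deg/s). Gravity (9.8 m/s^2) rides on the z axis.
#' Sampling is jittered within 70 +/- 5 Hz. Per-sample labels are returned;
#' windows spanning a transition can be excluded downstream.
#'
#' @param plan Data frame with columns `activity`, `duration_s`, in order.
#' @param seed Integer seed.
#' @param noiseSd Accelerometer noise SD, m/s^2 (default 0.3).
#' @param gyroNoiseSd Gyroscope noise SD, deg/s (default 5).
#' @param startUTC Recording start, UTC ms.
#' @return List with `recording` (30 s IMU chunks), `time` (s), `accel`,
#'   `gyro` (n x 3 each), and `labels` (per sample).
#' @export
genActivity <- function(plan, seed = 1, noiseSd = 0.3, gyroNoiseSd = 5,
                        startUTC = 1.7e12) {
  plan <- as.data.frame(plan)
  set.seed(seed)
  totalS <- sum(plan$duration_s)
  # one continuous jittered sampling clock for the whole recording:
  # per-sample spacing drawn within 70 +/- 5 Hz
  dt <- 1 / stats::runif(ceiling(totalS * 76) + 2, 65, 75)
  time <- cumsum(c(0, dt))
  time <- time[time < totalS]
  labels <- character(length(time))
  accel <- matrix(stats::rnorm(3 * length(time), 0, noiseSd),
                  ncol = 3)
  accel[, 3] <- accel[, 3] + 9.8
  gyro <- matrix(stats::rnorm(3 * length(time), 0, gyroNoiseSd), ncol = 3)
  tNow <- 0
  for (r in seq_len(nrow(plan))) {
    p <- .ACTIVITY_PARAMS[[plan$activity[r]]]
    if (is.null(p)) stop("unknown activity: ", plan$activity[r])
    dur <- plan$duration_s[r]
    sel <- which(time >= tNow & time < tNow + dur)
    labels[sel] <- plan$activity[r]
    if (p$amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      accel[sel, p$axis] <- accel[sel, p$axis] +
        p$amp * sin(2 * pi * p$freq * (time[sel] - tNow) + phase)
    }
    if (!is.null(p$gyro)) gyro[sel, 3] <- gyro[sel, 3] + p$gyro
    tNow <- tNow + dur
  }
  mag <- matrix(stats::rnorm(3 * length(time), 0, 0.05), ncol = 3)
  mag[, 1] <- mag[, 1] + 0.4  # constant field, a.u.
  imu <- cbind(accel, gyro, mag)
  colnames(imu) <- IMU_CHANNELS
  chunks <- list()
  k <- 0
  repeat {
    sel <- which(time >= k * 30 & time < (k + 1) * 30)
    if (!length(sel)) break
    chunks[[k + 1]] <- SensorChunk("imu", startUTC + k * 30000,
                                   startUTC + (k + 1) * 30000,
                                   imu[sel, , drop = FALSE])
    k <- k + 1
  }
  list(recording = Recording(chunks), time = time,
       accel = quantizeSamples("imu", imu)[, 1:3],
       gyro = quantizeSamples("imu", imu)[, 4:6], labels = labels)
}

#' Generate a windowed activity corpus with exact class counts
#'
#' Builds a per-class activity stream long enough for the requested number
#' of 5 s windows, runs the IMU preprocessing chain (gravity removal,
#' dynamic-rate resampling to 70 Hz, windowing with transition exclusion),
#' and trims to the exact class counts.
#'
#' @param counts Named integer vector of windows per class, e.g.
#'   `c(upright = 812, walk = 150, glide = 176, squat = 116)`.
#' @param seed Integer seed.
#' @param noiseSd Accelerometer noise SD, m/s^2.
#' @return List with `features` (windows x 1050 matrix), `label`, and
#'   `subject` (round-robin pseudo-subject ids).
#' @export
genActivityCorpus <- function(counts = c(upright = 812, walk = 150,
                                         glide = 176, squat = 116),
                              seed = 1, noiseSd = 0.3) {
  feats <- NULL; lab <- character()
  for (cl in names(counts)) {
    need <- counts[[cl]]
    # one long bout per class, padded so resampling + windowing still
    # yields at least `need` whole windows
    plan <- data.frame(activity = cl, duration_s = 5 * (need + 2))
    g <- genActivity(plan, seed = seed + match(cl, names(counts)),
                     noiseSd = noiseSd)
    rs <- resampleDynamic(g$time, g$accel, targetRate = 70, intervalS = 30)
    acc <- removeGravity(rs$values, rate = 70)
    w <- windowActivity(acc, rep(cl, nrow(acc)), rate = 70, windowS = 5)
    if (nrow(w$features) < need) stop("not enough windows generated")
    feats <- rbind(feats, w$features[seq_len(need), , drop = FALSE])
    lab <- c(lab, rep(cl, need))
  }
  list(features = feats, label = lab,
       subject = rep_len(paste0("s", 1:12), length(lab)))
}

#' Degrade a recording with sample loss and clock drift
#'
#' Drops samples in bursts at chunk tails (mimicking storage-write
#' stalls) until the requested missing rate is reached, and applies a
#' linear real-time-clock drift to all chunk timestamps. Surviving samples
#' are untouched.
#'
#' @param recording A valid [Recording-class].
#' @param missingRate Target fraction of samples dropped (must be < 0.5).
#' @param driftSPer12h Clock drift in seconds per 12 h (default 0).
#' @param seed Integer seed (per-chunk loss jitter).
#' @return List with `recording` (degraded), and `droppedIntervals` (per
#'   modality, a matrix of (start, end) seconds from recording start
#'   covering the dropped stretches).
#' @export
degradeRecording <- function(recording, missingRate, driftSPer12h = 0,
                             seed = 1) {
  if (missingRate >= 0.5) stop("missingRate must be below 0.5")
  if (missingRate < 0) stop("missingRate must be non-negative")
  set.seed(seed)
  origin <- if (length(recording@chunks))
    min(vapply(recording@chunks, startUTC, numeric(1))) else 0
  driftRate <- driftSPer12h / (12 * 3600)
  dropped <- list()
  newChunks <- lapply(recording@chunks, function(ch) {
    n <- chunkLength(ch)
    nDrop <- if (missingRate > 0)
      min(n - 1, stats::rbinom(1, n, missingRate)) else 0
    keep <- seq_len(n - nDrop)
    if (nDrop > 0) {
      t0 <- (ch@startUTC - origin) / 1000
      iv <- c(t0 + (n - nDrop) / ch@nominalRate, t0 + n / ch@nominalRate)
      dropped[[ch@modality]] <<- rbind(dropped[[ch@modality]], iv)
    }
    smp <- if (is.matrix(ch@samples)) ch@samples[keep, , drop = FALSE]
           else ch@samples[keep]
    SensorChunk(ch@modality,
                ch@startUTC + (ch@startUTC - origin) * driftRate,
                ch@endUTC + (ch@endUTC - origin) * driftRate,
                smp, ch@missingMask[keep], nominalRate = ch@nominalRate)
  })
  list(recording = Recording(newChunks,
                             firmwareVersion = recording@firmwareVersion,
                             deviceId = recording@deviceId),
       droppedIntervals = dropped)
}

.EMOTION_PARAMS <- list(
  neutral = list(f0 = 120, f0Slope = 0, vibrato = 0, energy = 0.30,
                 tilt = 1.2, jitter = 0.00),
  happy   = list(f0 = 220, f0Slope = 40, vibrato = 6, energy = 0.55,
                 tilt = 0.7, jitter = 0.01),
  sad     = list(f0 = 95, f0Slope = -25, vibrato = 0, energy = 0.18,
                 tilt = 1.8, jitter = 0.00),
  angry   = list(f0 = 180, f0Slope = 10, vibrato = 0, energy = 0.70,
                 tilt = 0.4, jitter = 0.04)
)

#' Generate a surrogate emotional-speech corpus
#'
#' Each utterance is a harmonic source with an emotion-dependent
#' fundamental-frequency contour, energy level, spectral tilt (harmonic
#' rolloff exponent) and jitter, plus broadband noise, amplitude-modulated
#' into syllable-like bursts. This is a parametric stand-in with the
#' class-separating acoustics of emotional speech, not a cry or speech
#' synthesizer.
#'
#' @param counts Named vector of utterances per emotion (default the
#'   4-class design `c(neutral = 28, happy = 37, sad = 38, angry = 38)`).
#' @param seed Integer seed.
#' @param rate Sampling rate, Hz (default 16000).
#' @param clipLevel Optional hard-clip level as a fraction of each
#'   utterance's peak (e.g. 0.7); `NULL` for no clipping.
#' @param separation Scale factor on inter-class parameter differences;
#'   0 collapses all classes onto the neutral parameters (chance-level
#'   corpus), 1 is the full separation.
#' @return List with `waveforms` (list), `emotion`, `speaker`, `rate`.
#' @export
genSpeechCorpus <- function(counts = c(neutral = 28, happy = 37,
                                       sad = 38, angry = 38),
                            seed = 1, rate = 16000, clipLevel = NULL,
                            separation = 1) {
  set.seed(seed)
  base <- .EMOTION_PARAMS$neutral
  waveforms <- list(); emotion <- character(); speaker <- character()
  speakers <- paste0("spk", 1:8)
  spkF0 <- stats::rnorm(8, 0, 10)
  u <- 0
  for (em in names(counts)) {
    p0 <- .EMOTION_PARAMS[[em]]
    p <- lapply(stats::setNames(names(base), names(base)), function(k)
      base[[k]] + separation * (p0[[k]] - base[[k]]))
    for (i in seq_len(counts[[em]])) {
      u <- u + 1
      spk <- speakers[(u - 1) %% 8 + 1]
      dur <- stats::runif(1, 1.2, 2.0)
      n <- round(dur * rate)
      t <- (seq_len(n) - 1) / rate
      f0 <- p$f0 + spkF0[(u - 1) %% 8 + 1] + p$f0Slope * t / dur +
        p$vibrato * sin(2 * pi * 5 * t)
      if (p$jitter > 0)
        f0 <- f0 * (1 + p$jitter * stats::rnorm(n))
      phase <- 2 * pi * cumsum(f0) / rate
      w <- numeric(n)
      for (h in 1:8) w <- w + h^(-p$tilt) * sin(h * phase)
      # syllable-like energy bursts at ~3 Hz
      env <- 0.4 + 0.6 * abs(sin(2 * pi * 1.5 * t + stats::runif(1, 0, pi)))
      w <- w * env
      w <- w / max(abs(w)) * p$energy
      w <- w + stats::rnorm(n, 0, 0.01)
      if (!is.null(clipLevel)) {
        lim <- clipLevel * max(abs(w))
        w <- pmin(pmax(w, -lim), lim)
      }
      waveforms[[u]] <- w
      emotion <- c(emotion, em)
      speaker <- c(speaker, spk)
    }
  }
  list(waveforms = waveforms, emotion = emotion, speaker = speaker,
       rate = rate)
}
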