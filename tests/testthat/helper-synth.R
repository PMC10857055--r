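# Shared fixtures, built in code.

# beat times for a prescribed sinusoidally modulated heart period
sineBeats <- function(durationS, baseMs = 800, ampMs = 100, hz = 0.25) {
  bt <- 0
  t <- 0
  while (t < durationS) {
    t <- t + (baseMs + ampMs * sin(2 * pi * hz * t)) / 1000
    bt <- c(bt, t)
  }
  bt
}

# a small multimodal recording with padding in the IMU chunk
smallRecording <- function(seed = 1, firmware = "v1") {
  set.seed(seed)
  ecg <- SensorChunk("ecg", 0, 30000, sample(0:4095, 72780, TRUE))
  aud <- SensorChunk("audio", 0, 10000, stats::runif(220500, -1, 1))
  m <- matrix(stats::rnorm(2100 * 9), ncol = 9,
              dimnames = list(NULL, triad:::IMU_CHANNELS))
  mask <- rep(FALSE, 2100); mask[100:150] <- TRUE
  imu <- SensorChunk("imu", 0, 30000, m, mask)
  Recording(list(ecg, aud, imu), firmwareVersion = firmware,
            deviceId = "devT")
}

# MAPE between a prescribed IBI series and a detected/edited IBISeries,
# both viewed as step functions of time on a common grid
ibiStepMape <- function(truthBeats, truthIbiMs, series, fromS, toS,
                        stepS = 0.5) {
  grid <- seq(fromS, toS, by = stepS)
  tv <- stats::approx(truthBeats[-length(truthBeats)], truthIbiMs, grid,
                      method = "constant", rule = 2)$y
  bt <- beatTimes(series)
  dv <- stats::approx(bt[-length(bt)], ibiMs(series), grid,
                      method = "constant", rule = 2)$y
  mean(abs(tv - dv) / tv) * 100
}

# all token sequences of length <= maxLen over a vocabulary
allTokenSeqs <- function(vocab, maxLen) {
  out <- list(character(0))
  for (l in seq_len(maxLen)) {
    g <- do.call(expand.grid, c(rep(list(vocab), l),
                                stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(g)), function(i)
      as.character(unlist(g[i, ]))))
  }
  out
}

# the printed pooled activity confusion matrix shipped as extdata
deviceConfusion <- function(which = "device") {
  f <- system.file("extdata",
                   sprintf("activity_confusion_%s.csv", which),
                   package = "triad")
  as.matrix(utils::read.csv(f, row.names = 1))
}
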