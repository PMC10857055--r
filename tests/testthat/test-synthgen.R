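test_that("the ECG generator honours its prescribed IBI schedule", {
  flat <- genEcg(data.frame(label = "s", duration_s = 60, base_ms = 800,
                            amp_ms = 0, hz = 0.25), seed = 1)
  expect_equal(unique(round(flat$ibiMs, 6)), 800)

  mod <- genEcg(data.frame(label = "s", duration_s = 120, base_ms = 800,
                           amp_ms = 100, hz = 0.25), seed = 1)
  expect_equal(min(mod$ibiMs), 700, tolerance = 0.01)
  expect_equal(max(mod$ibiMs), 900, tolerance = 0.01)
  expect_error(genEcg(data.frame(label = "s", duration_s = 60,
                                 base_ms = 500, amp_ms = 600, hz = 0.2)),
               "amplitude")

  # deterministic given seed
  a <- genEcg(data.frame(label = "s", duration_s = 60, base_ms = 800,
                         amp_ms = 50, hz = 0.3), noiseSd = 15, seed = 9)
  b <- genEcg(data.frame(label = "s", duration_s = 60, base_ms = 800,
                         amp_ms = 50, hz = 0.3), noiseSd = 15, seed = 9)
  expect_identical(a$recording, b$recording)
})

test_that("end-to-end generation, detection and RSA recover the closed form", {
  g <- genEcg(data.frame(label = "s", duration_s = 300, base_ms = 800,
                         amp_ms = 100, hz = 0.25), noiseSd = 10, seed = 2)
  ecg <- unlist(lapply(chunks(g$recording, "ecg"), chunkSamples))
  res <- computeRSA(IBISeries(detectRPeaks(ecg)), bandConfig("adult"))
  expect_lt(abs(taskMean(res) - log(100^2 / 2)), 0.15)
})

test_that("degradation hits the requested loss rate and conserves survivors", {
  g <- genEcg(data.frame(label = "s", duration_s = 300, base_ms = 800,
                         amp_ms = 100, hz = 0.25), noiseSd = 10, seed = 3)
  same <- degradeRecording(g$recording, missingRate = 0, seed = 4)
  expect_identical(same$recording, g$recording)

  for (rate in c(0.087, 0.023)) {
    deg <- degradeRecording(g$recording, missingRate = rate, seed = 5)
    expect_lt(abs(missingFraction(chunks(deg$recording, "ecg")) - rate),
              0.005)
    # surviving samples are bit-exact copies
    orig <- chunks(g$recording, "ecg")[[1]]
    kept <- chunks(deg$recording, "ecg")[[1]]
    expect_identical(chunkSamples(kept),
                     chunkSamples(orig)[seq_len(chunkLength(kept))])
  }
  expect_error(degradeRecording(g$recording, missingRate = 0.6), "0.5")
})

test_that("clock drift shifts the final timestamp linearly", {
  # sparse IMU chunks spanning 12 h
  mk <- function(t0) SensorChunk("imu", t0, t0 + 30000,
                                 matrix(0, 2100, 9))
  rec <- Recording(list(mk(0), mk(6 * 3600 * 1000),
                        mk(12 * 3600 * 1000)))
  deg <- degradeRecording(rec, missingRate = 0, driftSPer12h = 3)
  last <- chunks(deg$recording, "imu")[[3]]
  expect_equal(startUTC(last) - 12 * 3600 * 1000, 3000, tolerance = 100)
})

test_that("the speech corpus matches its class design and supports declipping", {
  corp <- genSpeechCorpus(seed = 6)
  expect_identical(as.integer(table(corp$emotion)[c("neutral", "happy",
                                                    "sad", "angry")]),
                   c(28L, 37L, 38L, 38L))
  expect_length(corp$waveforms, 141)

  clean <- genSpeechCorpus(counts = c(neutral = 2), seed = 7)
  clipped <- genSpeechCorpus(counts = c(neutral = 2), seed = 7,
                             clipLevel = 0.7)
  w0 <- clean$waveforms[[1]]
  wc <- clipped$waveforms[[1]]
  w1 <- declip(wc, 0.70)
  # restored peak amplitude within 5% of the unclipped truth, and the
  # waveform strictly closer to it than the clipped input
  expect_lt(abs(max(abs(w1)) - max(abs(w0))), 0.05 * max(abs(w0)))
  expect_lt(sqrt(mean((w1 - w0)^2)), 0.9 * sqrt(mean((wc - w0)^2)))

  a <- genSpeechCorpus(seed = 8); b <- genSpeechCorpus(seed = 8)
  expect_identical(a$waveforms, b$waveforms)
})

test_that("activity generation respects plans, jitter bounds and window counts", {
  g <- genActivity(data.frame(activity = c("upright", "walk"),
                              duration_s = c(60, 60)), seed = 10)
  expect_setequal(unique(g$labels), c("upright", "walk"))
  dt <- diff(g$time)
  expect_true(all(dt > 1 / 76 & dt < 1 / 64))

  corp <- genActivityCorpus(counts = c(upright = 10, walk = 5, glide = 5,
                                       squat = 5), seed = 11)
  expect_identical(as.integer(table(corp$label)[c("upright", "walk",
                                                  "glide", "squat")]),
                   c(10L, 5L, 5L, 5L))
  expect_identical(ncol(corp$features), 1050L)  # 5 s x 70 Hz x 3 axes
})
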