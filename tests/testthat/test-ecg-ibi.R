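test_that("clean constant-rhythm ECG yields tick-accurate IBI", {
  g <- genEcg(data.frame(label = "s", duration_s = 60, base_ms = 800,
                         amp_ms = 0, hz = 0.25), noiseSd = 0, seed = 1)
  ecg <- unlist(lapply(chunks(g$recording, "ecg"), chunkSamples))
  bt <- detectRPeaks(ecg)
  ibi <- round(diff(bt) * 1000)
  expect_true(all(ibi %in% c(796, 800, 804)))
  # >= 99% of detected beats within one 4 ms tick of a prescribed beat
  err <- vapply(bt, function(b) min(abs(g$beatTimes - b)), numeric(1))
  expect_gte(mean(err <= 0.0041), 0.99)
})

test_that("flat signals and short traces are rejected", {
  expect_error(detectRPeaks(rep(2048, 72780)), "flat")
  expect_error(detectRPeaks(rep(0, 72780)), "flat")
  expect_error(detectRPeaks(stats::rnorm(1000), rate = 2426), "10 s")
})

test_that("a 60 s trace at 75 bpm yields 75 +/- 1 beats", {
  g <- genEcg(data.frame(label = "s", duration_s = 60, base_ms = 800,
                         amp_ms = 100, hz = 0.25), noiseSd = 20, seed = 2)
  ecg <- unlist(lapply(chunks(g$recording, "ecg"), chunkSamples))
  expect_lte(abs(length(detectRPeaks(ecg)) - 75), 1)
})

test_that("forced divide and combine artifact cases are edited as expected", {
  long <- IBISeries(cumsum(c(0, 0.8, 0.8, 1.6, 0.8, 0.8, 0.8)))
  ed <- correctMissingArtifacts(long, subjectClass = "adult")
  expect_identical(ibiMs(ed), rep(800, 7))
  expect_identical(sum(ibiFlags(ed) == "edited_divide"), 2L)

  short <- IBISeries(cumsum(c(0, 0.8, 0.8, 0.4, 0.4, 0.8, 0.8)))
  ed2 <- correctMissingArtifacts(short, subjectClass = "adult")
  expect_identical(ibiMs(ed2), rep(800, 5))
  expect_identical(sum(ibiFlags(ed2) == "edited_combine"), 1L)
})

test_that("editing preserves total duration and is idempotent", {
  g <- genEcg(data.frame(label = "s", duration_s = 180, base_ms = 800,
                         amp_ms = 100, hz = 0.25), noiseSd = 20, seed = 3)
  deg <- degradeRecording(g$recording, missingRate = 0.02, seed = 4)
  ser <- extractIbi(deg$recording, "adult")
  expect_equal(sum(ibiMs(ser)) / 1000,
               diff(range(beatTimes(ser))), tolerance = 1e-6)
  twice <- correctMissingArtifacts(ser, subjectClass = "adult")
  expect_equal(ibiMs(twice), ibiMs(ser))
  expect_identical(isUnusable(ser), FALSE)
})

test_that("intervals overlapping padded stretches are flagged and repaired", {
  beats <- cumsum(c(0, rep(0.8, 20)))
  ser <- correctMissingArtifacts(IBISeries(beats),
                                 paddingIntervals = cbind(7.9, 8.3),
                                 subjectClass = "adult")
  expect_gte(editedFraction(ser), 1 / 21)
  # repaired values stay at the local rhythm
  expect_true(all(abs(ibiMs(ser) - 800) <= 100))
})

test_that("series needing more than the usable fraction of edits are marked unusable", {
  set.seed(5)
  vals <- rep(0.8, 40)
  vals[seq(1, 40, 3)] <- 1.9  # a third of the intervals wildly long
  expect_warning(ed <- correctMissingArtifacts(IBISeries(cumsum(c(0, vals)))),
                 "unusable")
  expect_true(isUnusable(ed))
})

test_that("session segmentation partitions intervals without double assignment", {
  bt <- sineBeats(12 * 60, 800, 100, 0.25)
  sess <- data.frame(label = c("baseline", "puzzle", "recovery", "matrices"),
                     start_s = c(0, 180, 420, 540),
                     end_s = c(180, 420, 540, 720))
  segs <- segmentSessions(IBISeries(bt), sess)
  expect_named(segs, sess$label)
  counts <- vapply(segs, function(s) length(ibiMs(s)), 1L)
  total <- length(bt) - 1
  expect_lte(abs(sum(counts) - total), length(segs))  # boundary beats only
  # durations roughly proportional to session lengths at ~75 bpm
  expect_equal(unname(counts / c(180, 240, 120, 180)), rep(75 / 60, 4),
               tolerance = 0.05)

  expect_warning(segs2 <- segmentSessions(IBISeries(bt),
                                          data.frame(label = "late",
                                                     start_s = 2000,
                                                     end_s = 2100)),
                 "no intervals")
  expect_length(ibiMs(segs2$late), 0)
  expect_error(segmentSessions(IBISeries(bt),
                               data.frame(label = c("a", "b"),
                                          start_s = c(0, 100),
                                          end_s = c(150, 200))),
               "overlap")
})

test_that("IBI series survive a CSV round-trip", {
  bt <- sineBeats(60)
  ser <- IBISeries(bt)
  ser@session <- rep("baseline", length(ibiMs(ser)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeIbiCsv(ser, f)
  back <- readIbiCsv(f)
  expect_equal(ibiMs(back), ibiMs(ser))
  expect_identical(ibiSession(back), ibiSession(ser))
})
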