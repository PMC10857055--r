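test_that("write/read round-trips are bit-exact, including masks and firmware flag", {
  for (seed in 1:3) {
    rec <- smallRecording(seed, firmware = if (seed %% 2) "v1" else "v2")
    f <- withr::local_tempfile()
    writeRecording(rec, f)
    rec2 <- readRecording(f)
    expect_identical(rec2, rec)
    # write o read o write is byte-identical
    f2 <- withr::local_tempfile()
    writeRecording(rec2, f2)
    expect_identical(readBin(f2, "raw", file.size(f2)),
                     readBin(f, "raw", file.size(f)))
  }
})

test_that("empty recording and a lone full-size ECG chunk round-trip", {
  f <- withr::local_tempfile()
  empty <- Recording(list(), firmwareVersion = "v2", deviceId = "e0")
  writeRecording(empty, f)
  expect_identical(readRecording(f), empty)

  ecg <- SensorChunk("ecg", 0, 30000, rep(2048, 72780))
  expect_identical(chunkLength(ecg), 72780L)  # 30 s x 2426 Hz
  rec <- Recording(list(ecg))
  writeRecording(rec, f)
  expect_identical(chunkSamples(chunks(readRecording(f), "ecg")[[1]]),
                   chunkSamples(ecg))
})

test_that("truncated file drops the trailing chunk with a warning; bad magic errors", {
  rec <- smallRecording(4)
  f <- withr::local_tempfile()
  writeRecording(rec, f)
  bytes <- readBin(f, "raw", file.size(f))
  f3 <- withr::local_tempfile()
  writeBin(bytes[seq_len(length(bytes) - 5000)], f3)
  expect_warning(rec2 <- readRecording(f3), "truncated")
  expect_identical(length(chunks(rec2)), length(chunks(rec)) - 1L)
  expect_identical(chunks(rec2)[[1]], chunks(rec)[[1]])

  f4 <- withr::local_tempfile()
  writeBin(charToRaw("NOPEnope"), f4)
  expect_error(readRecording(f4), "magic")
})

test_that("export writes CSVs with one row per sample and a WAV with one frame per sample", {
  rec <- smallRecording(5)
  d <- withr::local_tempdir()
  files <- exportRecording(rec, d)
  ecg <- utils::read.csv(files[["ecg"]])
  expect_identical(nrow(ecg), 72780L)
  expect_named(ecg, c("utc_ms", "adc", "padded"))
  imu <- utils::read.csv(files[["imu"]])
  expect_identical(nrow(imu), 2100L)
  expect_identical(sum(imu$padded), 51L)
  wav <- readWav(files[["audio"]])
  expect_identical(length(wav$samples), 220500L)  # 10 s x 22050 Hz
  expect_identical(wav$rate, 22050)

  # modality absent -> no file
  d2 <- withr::local_tempdir()
  files2 <- exportRecording(Recording(chunks(rec, "ecg")), d2)
  expect_false("audio" %in% names(files2))
  expect_false(file.exists(file.path(d2, "audio.wav")))
})

test_that("missingFraction matches the expected-sample arithmetic and ignores chunk order", {
  # 30 s chunk at a rate chosen so the UTC span implies 1000 samples
  mk <- function(nObs) SensorChunk("ecg", 0, 30000, rep(100, nObs),
                                   nominalRate = 1000 / 30)
  expect_identical(missingFraction(mk(1000)), 0)
  expect_equal(missingFraction(mk(913)), 0.087)
  expect_equal(missingFraction(mk(977)), 0.023)

  rec <- smallRecording(6)
  ch <- chunks(rec)
  expect_identical(missingFraction(ch), missingFraction(rev(ch)))
  expect_error(missingFraction(list()), "at least one")
})

test_that("padded samples must be zero and chunk periods are enforced", {
  expect_error(methods::new("SensorChunk", modality = "ecg", startUTC = 0,
                            endUTC = 30000, nominalRate = 2426,
                            samples = rep(5, 72780),
                            missingMask = rep(TRUE, 72780)),
               "zero")
  expect_error(SensorChunk("audio", 0, 30000, numeric(661500)), "period")
})

test_that("WAV files round-trip through the PCM writer/reader", {
  x <- sin(2 * pi * 440 * (0:22049) / 22050) * 0.5
  f <- withr::local_tempfile(fileext = ".wav")
  writeWav(x, f, 22050)
  w <- readWav(f)
  expect_identical(w$rate, 22050)
  expect_equal(w$samples, x, tolerance = 1e-4)  # 16-bit quantization
})
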